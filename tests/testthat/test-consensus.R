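mk_sol <- function(col_sets, n_cols) {
  bic <- lapply(col_sets, function(cs) list(rows = 1L, cols = cs, score = 1))
  promclust:::new_bicluster_solution(bic, 1L, n_cols, "test", 1L)
}

test_that("confusion_matrix equals brute-force intersection counts", {
  a <- mk_sol(list(1:5, 6:12), 20)
  expect_equal(confusion_matrix(a, a), diag(c(5L, 7L)), ignore_attr = TRUE)
  b1 <- mk_sol(list(1:4), 10)
  b2 <- mk_sol(list(1:2, 3:4), 10)
  expect_equal(confusion_matrix(b1, b2), matrix(c(2L, 2L), 1), ignore_attr = TRUE)
  set.seed(5)
  for (i in 1:20) {
    n <- 30
    ka <- sample(2:4, 1)
    kb <- sample(2:4, 1)
    la <- split(sample(n, 20), sample(ka, 20, replace = TRUE))
    lb <- split(sample(n, 18), sample(kb, 18, replace = TRUE))
    sa <- mk_sol(la, n)
    sb <- mk_sol(lb, n)
    cm <- confusion_matrix(sa, sb)
    for (x in seq_along(la)) for (y in seq_along(lb)) {
      expect_equal(cm[x, y], length(intersect(la[[x]], lb[[y]])))
    }
  }
  expect_error(confusion_matrix(mk_sol(list(1:2), 5), mk_sol(list(1:2), 6)),
               "universe")
})

test_that("assign_clusters solves the LAP optimally on small grids", {
  r <- assign_clusters(matrix(c(5, 0, 0, 7), 2))
  expect_equal(r$assignment, 1:2)
  expect_equal(r$total_overlap, 12)
  r2 <- assign_clusters(matrix(c(0, 7, 5, 0), 2))
  expect_equal(r2$assignment, c(2L, 1L))
  expect_equal(r2$total_overlap, 12)
  set.seed(31)
  for (i in 1:100) {
    ka <- sample(2:4, 1)
    kb <- sample(2:4, 1)
    M <- matrix(stats::rpois(ka * kb, 4), ka, kb)
    got <- assign_clusters(M)$total_overlap
    expect_equal(got, lap_oracle(M), info = paste("grid", i))
  }
  expect_error(assign_clusters(matrix(-1, 2, 2)), "non-negative")
})

test_that("consensus with identical runs retains every column at frequency 1", {
  # noise-free planted blocks make the ssvd engine deterministic
  X <- matrix(0, 10, 40)
  X[1:3, 1:12] <- 1
  X[4:6, 13:22] <- 0.9
  single <- run_ssvd(X, seed = 1)
  cons <- consensus_biclust(X, engine = "ssvd", n_runs = 5, seed = 2)
  expect_equal(sort(cons$retained_cols$index),
               sort(unlist(lapply(single$biclusters, function(b) b$cols))))
  expect_true(all(cons$retained_cols$frequency == 1))
  # frequencies per column sum to at most 1
  expect_true(all(rowSums(cons$column_frequency) <= 1 + 1e-12))
})

test_that("consensus is reproducible and respects the frequency threshold", {
  pm <- planted_3block(120, 18, noise_sd = 0.15, background_rate = 0.02, seed = 21,
                       block_cols = c(35, 30, 25))
  c1 <- consensus_biclust(pm$matrix, engine = "ssvd", n_runs = 6, seed = 5)
  c2 <- consensus_biclust(pm$matrix, engine = "ssvd", n_runs = 6, seed = 5)
  expect_identical(c1$retained_cols, c2$retained_cols)
  expect_identical(c1$row_tests, c2$row_tests)
  # monotonicity: raising min_freq only removes columns
  ids <- function(x) x$retained_cols$id
  f3 <- filter_consensus(c1, 0.3)
  f5 <- filter_consensus(c1, 0.5)
  f7 <- filter_consensus(c1, 0.7)
  expect_true(all(ids(f5) %in% ids(f3)))
  expect_true(all(ids(f7) %in% ids(f5)))
})

test_that("zero-cluster engines yield an empty consensus without error", {
  X <- matrix(0, 6, 10)
  cons <- consensus_biclust(X, engine = "ssvd", n_runs = 3, seed = 1)
  expect_equal(nrow(cons$retained_cols), 0)
  expect_null(cons$target)
})

test_that("row_cluster_ttest matches the closed-form value", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1)
  got <- row_cluster_ttest(X, 1:3, 1)
  s <- sqrt(1 / 3 + 1 / 3)
  expect_equal(got$t, -3 / s, tolerance = 1e-6)
  # identical constant groups: p = 1, bar height 0
  flat <- row_cluster_ttest(matrix(1, 1, 8), 1:4, 1)
  expect_equal(flat$p, 1)
  expect_equal(flat$neglog10p, 0)
  # bar height is -log10 p by definition
  expect_equal(-log10(got$p), got$neglog10p)
  expect_error(row_cluster_ttest(X, 1:6, 1), "proper subset")
})

test_that("order_heatmap groups by cluster with boundaries at block sizes", {
  X <- matrix(0, 8, 30)
  X[1:3, 1:12] <- 1
  X[4:6, 13:22] <- 0.9
  cons <- consensus_biclust(X, engine = "ssvd", n_runs = 4, seed = 3)
  lay <- order_heatmap(X, cons)
  expect_equal(lay$col_boundaries, c(12, 22))
  expect_setequal(lay$col_order[1:12], 1:12)
  expect_setequal(lay$col_order[13:22], 13:22)
  expect_setequal(lay$col_order[23:30], 23:30)
  expect_equal(lay$row_boundaries, c(3, 6))
  # single cluster covering everything sorts by mean signal
  X1 <- matrix(stats::runif(50, 0.5, 1), 5, 10)
  cons1 <- list(retained_cols = tibble::tibble(index = 1:10, id = as.character(1:10),
                                               cluster = 1L, frequency = 1),
                retained_rows = tibble::tibble(index = 1:5, id = as.character(1:5),
                                               cluster = 1L, frequency = 1))
  lay1 <- order_heatmap(X1, cons1)
  expect_equal(lay1$col_order, order(-colMeans(X1)))
})

test_that("tidy and glance summarize consensus objects", {
  X <- matrix(0, 6, 20)
  X[1:3, 1:8] <- 1
  cons <- consensus_biclust(X, engine = "ssvd", n_runs = 3, seed = 1)
  td <- tidy(cons)
  expect_true(all(c("dimension", "index", "cluster", "frequency") %in% names(td)))
  gl <- glance(cons)
  expect_equal(gl$n_retained_cols, nrow(cons$retained_cols))
  expect_s3_class(autoplot(cons, X), "ggplot")
})
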