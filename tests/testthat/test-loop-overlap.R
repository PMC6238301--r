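loop_row <- function(id, sA, eA, sB, eB, chrom = "chr1") {
  tibble::tibble(id = id, chromA = chrom, startA = sA, endA = eA,
                 chromB = chrom, startB = sB, endB = eB)
}

test_that("promoter_loops finds anchor overlaps and labels the remote side", {
  loops <- dplyr::bind_rows(
    loop_row("l1", 900, 1100, 50000, 51000),
    loop_row("l2", 70000, 71000, 980, 1200),
    loop_row("l3", 30000, 31000, 40000, 41000)
  )
  prom <- list(chrom = "chr1", start = 1000, end = 1200)
  got <- promoter_loops(prom, loops)
  expect_setequal(got$id, c("l1", "l2"))
  expect_equal(got$remote_start[got$id == "l1"], 50000)
  expect_equal(got$remote_start[got$id == "l2"], 70000)
  none <- promoter_loops(list(chrom = "chr1", start = 5000, end = 5100), loops)
  expect_equal(nrow(none), 0)
  # different chromosome never overlaps
  other <- promoter_loops(list(chrom = "chr2", start = 900, end = 1100), loops)
  expect_equal(nrow(other), 0)
})

test_that("select_loop maximizes remote H3K27ac with leftmost tie-break", {
  loops <- dplyr::bind_rows(
    loop_row("a", 900, 1100, 10000, 11000),
    loop_row("b", 900, 1100, 20000, 21000),
    loop_row("c", 900, 1100, 30000, 31000)
  )
  pl <- promoter_loops(list(chrom = "chr1", start = 950, end = 1050), loops)
  cov <- tibble::tibble(chrom = "chr1", start = c(10000, 20000, 30000),
                        end = c(11000, 21000, 31000), value = c(3, 9, 5))
  expect_equal(select_loop(pl, cov)$id, "b")
  expect_equal(select_loop(pl[1, ], cov)$id, "a")
  tie <- dplyr::mutate(cov, value = c(7, 7, 1))
  expect_equal(select_loop(pl, tie)$id, "a")
})

test_that("enhancer_class pads and applies strong > weak > none", {
  enh <- tibble::tibble(chrom = "chr1", start = c(1600, 400), end = c(1800, 480),
                        state = c("strong", "weak"))
  remote <- list(chrom = "chr1", start = 1000, end = 1200)
  expect_equal(enhancer_class(remote, enh, pad = 500), "strong")
  weak_only <- tibble::tibble(chrom = "chr1", start = 1600, end = 1800,
                              state = "weak")
  expect_equal(enhancer_class(remote, weak_only, pad = 500), "weak")
  expect_equal(enhancer_class(remote, enh[0, ], pad = 500), "none")
  # both within reach: strong wins
  both <- tibble::tibble(chrom = "chr1", start = c(1100, 1150), end = c(1120, 1180),
                         state = c("weak", "strong"))
  expect_equal(enhancer_class(remote, both, pad = 0), "strong")
  # padding monotonicity: class only escalates none -> weak -> strong
  rank <- c(none = 0, weak = 1, strong = 2)
  set.seed(12)
  for (i in 1:20) {
    enh_r <- tibble::tibble(chrom = "chr1",
                            start = sample(0:3000, 3),
                            state = sample(c("strong", "weak"), 3, TRUE))
    enh_r$end <- enh_r$start + 80
    cls <- vapply(c(0, 250, 500, 1000), function(p) {
      enhancer_class(remote, enh_r, pad = p)
    }, character(1))
    expect_true(all(diff(rank[cls]) >= 0))
  }
})

test_that("center_remote picks the coverage argmax with stated fallbacks", {
  remote <- list(chrom = "chr1", start = 4000, end = 6000)
  cov <- tibble::tibble(chrom = "chr1", start = c(4000, 5000), end = c(6000, 5001),
                        value = c(1, 50))
  got <- center_remote(remote, cov, flank = 1000)
  expect_equal(got$center, 5000)
  expect_equal(c(got$start, got$end), c(4000, 6000))
  flat <- tibble::tibble(chrom = "chr1", start = 3000, end = 7000, value = 2)
  expect_equal(center_remote(remote, flat)$center, 4000)  # leftmost max
  nocov <- center_remote(remote, cov[0, ])
  expect_true(nocov$flagged)
  expect_equal(nocov$center, 5000)  # geometric midpoint
})

test_that("loop pipeline output equals generator ground truth exactly", {
  proms <- tibble::tibble(id = paste0("p", 1:8), chrom = "chrS",
                          start = seq(1000, 71000, by = 10000),
                          end = seq(2000, 72000, by = 10000))
  ml <- make_loops(proms, 30, c(0.5, 0.3, 0.2), seed = 9)
  lr <- loop_report(proms, ml$loops, ml$enhancers, ml$h3k27ac, ml$ctcf)
  rep <- dplyr::filter(lr$report, n_loops > 0)
  sel_truth <- ml$truth$selected
  got_sel <- rep[match(sel_truth$promoter_id, rep$id), ]
  expect_equal(got_sel$loop_id, sel_truth$selected_loop)
  # classes and centers of the selected loops match per-loop truth
  lt <- ml$truth$loops[match(rep$loop_id, ml$truth$loops$loop_id), ]
  expect_equal(rep$enhancer_class, lt$enhancer_class)
  expect_equal(rep$center, lt$ctcf_center)
  # per-loop class proportions equal the exact generator allocation
  classes <- vapply(seq_len(nrow(ml$loops)), function(i) {
    enhancer_class(list(chrom = ml$loops$chromB[i], start = ml$loops$startB[i],
                        end = ml$loops$endB[i]), ml$enhancers, pad = 500)
  }, character(1))
  expect_equal(unname(table(classes)[c("strong", "weak", "none")]),
               c(15L, 9L, 6L), ignore_attr = TRUE)
  expect_equal(classes, ml$truth$loops$enhancer_class)
})
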