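test_that("noise-free planted block is exact and seed-independent", {
  cfg1 <- synthetic_config(5, 5, list(list(n_rows = 2, n_cols = 3, mean_signal = 1)),
                           noise_sd = 0, background_rate = 0, seed = 1)
  cfg2 <- synthetic_config(5, 5, list(list(n_rows = 2, n_cols = 3, mean_signal = 1)),
                           noise_sd = 0, background_rate = 0, seed = 999)
  m1 <- make_planted_matrix(cfg1)$matrix
  m2 <- make_planted_matrix(cfg2)$matrix
  expect_equal(sum(m1 == 1), 6)
  expect_equal(sum(m1 == 0), 19)
  expect_identical(unclass(m1), unclass(m2))
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- synthetic_config(40, 12, list(
    list(n_rows = 3, n_cols = 10, mean_signal = 0.8),
    list(n_rows = 3, n_cols = 8, mean_signal = 0.9),
    list(n_rows = 3, n_cols = 6, mean_signal = 0.7)
  ), noise_sd = 0.1, background_rate = 0.05, seed = 7)
  expect_identical(make_planted_matrix(cfg), make_planted_matrix(cfg))
  expect_identical(make_toy_genome(10, seed = 4), make_toy_genome(10, seed = 4))
  pm <- make_planted_matrix(cfg)
  expect_identical(
    make_expression(pm$matrix, c(1, 4), c(1, 2), noise_sd = 0.05, seed = 3),
    make_expression(pm$matrix, c(1, 4), c(1, 2), noise_sd = 0.05, seed = 3)
  )
  proms <- tibble::tibble(id = paste0("p", 1:5), chrom = "chrS",
                          start = seq(1000, 41000, by = 10000),
                          end = seq(2000, 42000, by = 10000))
  expect_identical(make_loops(proms, 12, c(0.5, 0.3, 0.2), seed = 2),
                   make_loops(proms, 12, c(0.5, 0.3, 0.2), seed = 2))
})

test_that("planted block cell means approach mean_signal over seeds", {
  # mean of clipped N(0.6, 0.1) cells over many draws stays near 0.6
  vals <- unlist(lapply(1:30, function(s) {
    cfg <- synthetic_config(20, 10, list(list(n_rows = 4, n_cols = 8, mean_signal = 0.6)),
                            noise_sd = 0.1, background_rate = 0, seed = s)
    m <- make_planted_matrix(cfg)$matrix
    m[1:4, 1:8]
  }))
  expect_lt(abs(mean(vals) - 0.6), 3 * 0.1 / sqrt(length(vals)) + 0.01)
})

test_that("block dimension violations raise errors", {
  expect_error(synthetic_config(5, 5, list(list(n_rows = 6, n_cols = 3, mean_signal = 1))),
               "exceed")
  expect_error(synthetic_config(5, 5, list(list(n_rows = 2, n_cols = 3, mean_signal = 1.5))),
               "mean_signal")
})

test_that("toy genome ground truth covers every rule at least once", {
  tg <- make_toy_genome(8, seed = 1)
  expect_setequal(tg$truth$scenario, promclust:::toy_scenarios)
  expect_true(all(c("active", "low", "inactive") %in% tg$truth$activity))
  expect_true(any(tg$truth$refseq_excluded))
  expect_setequal(setdiff(unique(tg$truth$cage_exclusion), "none"),
                  c("mixed_strand", "span", "multi_gene"))
  # robust peaks are a subset of the permissive tier by construction
  expect_true(all(tg$robust_peaks$start %in% tg$permissive_peaks$start))
})

test_that("expression generator follows the linear model exactly", {
  cfg <- synthetic_config(30, 8, list(list(n_rows = 8, n_cols = 30, mean_signal = 0.5)),
                          noise_sd = 0.2, background_rate = 0, seed = 5)
  pm <- make_planted_matrix(cfg)
  z <- make_expression(pm$matrix, c(2, 5), c(0, 0), noise_sd = 0, seed = 1)
  expect_equal(unname(z$expression), rep(0, 30))
  one <- make_expression(pm$matrix, 3, 1, noise_sd = 0, seed = 1)
  expect_equal(unname(one$expression), unname(unclass(pm$matrix)[3, ]))
  expect_error(make_expression(pm$matrix, c(1, 2), 1), "one entry per predictor")
  expect_error(make_expression(pm$matrix, 99, 1), "row indices")
})

test_that("loop generator records exact class proportions and selection truth", {
  proms <- tibble::tibble(id = paste0("p", 1:6), chrom = "chrS",
                          start = seq(1000, 51000, by = 10000),
                          end = seq(2000, 52000, by = 10000))
  ml <- make_loops(proms, 20, c(1, 0, 0), seed = 3)
  expect_true(all(ml$truth$loops$enhancer_class == "strong"))
  ml2 <- make_loops(proms, 20, c(0.5, 0.25, 0.25), seed = 3)
  expect_equal(as.integer(table(ml2$truth$loops$enhancer_class)[c("strong", "weak", "none")]),
               c(10L, 5L, 5L))
  # the truth-selected loop per promoter carries the maximal remote H3K27ac
  sel <- dplyr::left_join(ml2$truth$selected, ml2$truth$loops,
                          by = c("selected_loop" = "loop_id"))
  by_prom <- dplyr::group_by(ml2$truth$loops, promoter_id)
  mx <- dplyr::summarise(by_prom, mx = max(h3k27ac_mean))
  cmp <- dplyr::left_join(sel, mx, by = c("promoter_id.x" = "promoter_id"))
  expect_equal(cmp$h3k27ac_mean, cmp$mx)
  expect_error(make_loops(proms[0, ], 5), "empty")
})
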