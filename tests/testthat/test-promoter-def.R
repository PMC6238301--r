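test_that("TSS isolation filter drops crowded groups and is idempotent", {
  tss <- tibble::tibble(chrom = "chr1", pos = c(1000, 1800), strand = "+",
                        gene_id = c("g1", "g2"))
  expect_equal(nrow(filter_isolated_tss(tss)), 0)
  single <- tss[1, ]
  expect_equal(filter_isolated_tss(single), single)
  spread <- tibble::tibble(chrom = "chr1", pos = c(0, 1500, 3000), strand = "+",
                           gene_id = paste0("g", 1:3))
  expect_equal(nrow(filter_isolated_tss(spread)), 3)
  # exactly at the limit: distance 1000 counts as crowded
  lim <- tibble::tibble(chrom = "chr1", pos = c(0, 1000), strand = "+",
                        gene_id = c("g1", "g2"))
  expect_equal(nrow(filter_isolated_tss(lim)), 0)
  # different chromosomes never crowd each other
  two_chr <- tibble::tibble(chrom = c("chr1", "chr2"), pos = c(100, 300),
                            strand = "+", gene_id = c("g1", "g2"))
  expect_equal(nrow(filter_isolated_tss(two_chr)), 2)
  once <- filter_isolated_tss(spread)
  expect_equal(filter_isolated_tss(once), once)
})

test_that("activity calling follows the tiered-peak rule", {
  rob <- tibble::tibble(chrom = "chr1", start = 1090, end = 1110)
  perm <- dplyr::bind_rows(rob, tibble::tibble(chrom = "chr1", start = 940, end = 960))
  expect_equal(call_activity("chr1", 1000, robust_peaks = rob, permissive_peaks = perm), "active")
  none <- rob[0, ]
  expect_equal(call_activity("chr1", 1000, robust_peaks = none, permissive_peaks = perm), "low")
  expect_equal(call_activity("chr1", 1000, robust_peaks = none, permissive_peaks = none), "inactive")
  # peak outside the +/-500 window does not count
  far <- tibble::tibble(chrom = "chr1", start = 1600, end = 1620)
  expect_equal(call_activity("chr1", 1000, robust_peaks = far, permissive_peaks = far), "inactive")
  # strand-specific mode ignores opposite-strand peaks
  rob_minus <- tibble::tibble(chrom = "chr1", start = 1090, end = 1110, strand = "-")
  expect_equal(call_activity("chr1", 1000, strand = "+", robust_peaks = rob_minus,
                             permissive_peaks = rob_minus, strand_specific = TRUE),
               "inactive")
})

test_that("CAGE clustering chains with <200 bp gaps and flags exclusions", {
  tss3 <- tibble::tibble(chrom = "chr1", pos = c(100, 250, 400), strand = "+",
                         gene_id = "g1")
  cl <- cluster_cage_tss(tss3)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$span, 300)
  expect_equal(cl$exclusion_reason, "none")
  mixed <- tibble::tibble(chrom = "chr1", pos = c(100, 250), strand = c("+", "-"),
                          gene_id = "g1")
  expect_equal(cluster_cage_tss(mixed)$exclusion_reason, "mixed_strand")
  chain <- tibble::tibble(chrom = "chr1", pos = seq(0, 1140, by = 190), strand = "+",
                          gene_id = "g1")
  cc <- cluster_cage_tss(chain)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$span, 1140)
  expect_equal(cc$exclusion_reason, "span")
  multi <- tibble::tibble(chrom = "chr1", pos = c(100, 250), strand = "+",
                          gene_id = c("g1", "g2"))
  expect_equal(cluster_cage_tss(multi)$exclusion_reason, "multi_gene")
  # a missing gene assignment excludes rather than errors
  na_gene <- tibble::tibble(chrom = "chr1", pos = c(100, 250), strand = "+",
                            gene_id = c("g1", NA))
  expect_equal(cluster_cage_tss(na_gene)$exclusion_reason, "multi_gene")
  # a gap of exactly 200 does not chain
  gap200 <- tibble::tibble(chrom = "chr1", pos = c(0, 200), strand = "+",
                           gene_id = "g1")
  expect_equal(nrow(cluster_cage_tss(gap200)), 2)
})

test_that("every retained cluster satisfies span, strand and gene invariants", {
  tg <- make_toy_genome(24, seed = 2)
  cl <- cluster_cage_tss(tg$tss, tg$robust_peaks, tg$permissive_peaks)
  kept <- dplyr::filter(cl, status != "excluded")
  expect_true(all(kept$span <= 1000))
  expect_true(all(kept$strand %in% c("+", "-")))
  expect_true(all(!is.na(kept$gene_id)))
  expect_true(all(kept$status %in% c("active", "low", "inactive")))
})

test_that("computed statuses equal toy-genome ground truth exactly", {
  tg <- make_toy_genome(16, seed = 6)
  # RefSeq pipeline: isolated-scenario genes keep their truth activity
  pr <- define_promoters_refseq(tg$tss, tg$robust_peaks, tg$permissive_peaks,
                                tg$gene_spans)
  truth <- tg$truth
  retained_truth <- dplyr::filter(truth, !refseq_excluded)
  expect_setequal(unique(pr$gene_id), retained_truth$gene_id)
  got <- dplyr::distinct(dplyr::left_join(pr, truth, by = "gene_id")[, c("gene_id", "status", "activity")])
  expect_equal(got$status, got$activity)
  # CAGE pipeline: exclusion reasons and per-cluster statuses match truth
  cl <- cluster_cage_tss(tg$tss, tg$robust_peaks, tg$permissive_peaks)
  by_gene <- dplyr::filter(cl, !is.na(gene_id))
  joined <- dplyr::left_join(by_gene, truth, by = "gene_id")
  scn <- dplyr::filter(joined, scenario %in% c("active_isolated", "low_isolated",
                                               "inactive_isolated", "cage_run",
                                               "mixed_strand", "long_chain"))
  for (i in seq_len(nrow(scn))) {
    if (scn$cage_exclusion[i] == "none") {
      expect_equal(scn$status[i], scn$activity[i], info = scn$gene_id[i])
    } else {
      expect_equal(scn$exclusion_reason[i], scn$cage_exclusion[i], info = scn$gene_id[i])
    }
  }
})

test_that("reduce_inactive drops zero inactive columns and collapses duplicates", {
  m <- matrix(c(0, 0,   0.5, 0.2,  0.5, 0.2,  0, 0), nrow = 2,
              dimnames = list(c("e1", "e2"), c("p1", "p2", "p3", "p4")))
  sm <- signal_matrix(m)
  info <- tibble::tibble(id = paste0("p", 1:4),
                         status = c("inactive", "active", "active", "active"),
                         cluster_id = c("c1", "c2", "c2", "c3"),
                         pos = c(10, 20, 30, 40))
  red <- reduce_inactive(sm, info)
  # p1: inactive all-zero -> dropped; p3 duplicates p2 within c2 -> dropped;
  # p4: active all-zero -> retained
  expect_equal(colnames(red), c("p2", "p4"))
  # duplicate columns in different clusters are both kept
  info2 <- dplyr::mutate(info, cluster_id = c("c1", "c2", "c9", "c3"))
  expect_equal(colnames(reduce_inactive(sm, info2)), c("p2", "p3", "p4"))
})
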