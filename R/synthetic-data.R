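#' Synthetic-data generators with known ground truth
#'
#' These generators emulate the statistical structure of the real inputs of a
#' promoter-occupancy study -- block-structured occupancy matrices over a
#' sparse background, clustered TSSs with tiered CAGE peaks, expression driven
#' linearly by a few tracks, and chromatin loops whose remote anchors carry
#' enhancer marks -- so that every downstream stage can be tested against a
#' recorded ground truth without any external download.
#'
#' @name synthetic-data
NULL

#' Configuration for a planted-bicluster matrix
#'
#' @param n_promoters,n_experiments Matrix dimensions (columns are promoters).
#' @param blocks List of planted biclusters, each `list(n_rows, n_cols,
#'   mean_signal)` with `mean_signal` in (0, 1\]. Blocks occupy disjoint row
#'   and column sets.
#' @param noise_sd SD of additive Gaussian noise inside blocks.
#' @param background_rate Probability that a background cell carries a
#'   spurious small peak instead of exact 0.
#' @param seed RNG seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_promoters, n_experiments, blocks,
                             noise_sd = 0.1, background_rate = 0.02,
                             seed = 1L) {
  stopifnot(n_promoters >= 1, n_experiments >= 1, noise_sd >= 0,
            background_rate >= 0, background_rate <= 1)
  for (b in blocks) {
    if (b$mean_signal <= 0 || b$mean_signal > 1) {
      abort("block mean_signal must be in (0, 1]")
    }
  }
  if (sum(vapply(blocks, `[[`, numeric(1), "n_rows")) > n_experiments ||
      sum(vapply(blocks, `[[`, numeric(1), "n_cols")) > n_promoters) {
    abort("blocks exceed matrix dimensions")
  }
  structure(list(n_promoters = n_promoters, n_experiments = n_experiments,
                 blocks = blocks, noise_sd = noise_sd,
                 background_rate = background_rate, seed = seed),
            class = "synthetic_config")
}

#' Generate a planted-bicluster signal matrix
#'
#' Places the configured blocks on disjoint, consecutive row and column index
#' ranges. Cells inside block `b` are `mean_signal + N(0, noise_sd)`, clipped
#' to \[0, 1\]. Background cells are exactly 0 except with probability
#' `background_rate`, in which case they carry a small spurious peak
#' (Uniform(0.05, 0.25)), mimicking the sparse false-positive calls of real
#' peak-call matrices. Output is bit-identical for a fixed seed, and
#' independent of the seed when it is noise-free.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `matrix` (a [signal_matrix()]) and `truth`,
#'   a list holding `column_labels` and `row_labels` (block id or
#'   `"background"` per column/row) plus the config.
#' @export
make_planted_matrix <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_r <- config$n_experiments
  n_c <- config$n_promoters
  col_labels <- rep("background", n_c)
  row_labels <- rep("background", n_r)
  with_seed(substream_seed(config$seed, "planted_matrix"), {
    m <- matrix(0, n_r, n_c)
    if (config$background_rate > 0) {
      spurious <- stats::runif(n_r * n_c) < config$background_rate
      m[spurious] <- stats::runif(sum(spurious), 0.05, 0.25)
    }
    r0 <- 0L
    c0 <- 0L
    for (b in seq_along(config$blocks)) {
      blk <- config$blocks[[b]]
      rows <- r0 + seq_len(blk$n_rows)
      cols <- c0 + seq_len(blk$n_cols)
      vals <- blk$mean_signal
      if (config$noise_sd > 0) {
        vals <- vals + stats::rnorm(blk$n_rows * blk$n_cols, 0, config$noise_sd)
      }
      m[rows, cols] <- pmin(1, pmax(0, vals))
      col_labels[cols] <- paste0("block", b)
      row_labels[rows] <- paste0("block", b)
      r0 <- r0 + blk$n_rows
      c0 <- c0 + blk$n_cols
    }
    m
  }) -> m
  sm <- signal_matrix(m,
                      row_ids = sprintf("exp%02d", seq_len(n_r)),
                      col_ids = sprintf("prom%04d", seq_len(n_c)))
  list(matrix = sm,
       truth = list(column_labels = stats::setNames(col_labels, colnames(sm)),
                    row_labels = stats::setNames(row_labels, rownames(sm)),
                    config = config))
}

# scenario battery cycled over genes by make_toy_genome; each scenario is laid
# out in its own 100 kb tile so rules never interact across genes
toy_scenarios <- c("active_isolated", "low_isolated", "inactive_isolated",
                   "crowded_pair", "cage_run", "mixed_strand",
                   "long_chain", "multi_gene")

#' Generate a toy genome exercising every promoter-definition rule
#'
#' Lays out `n_genes` genes on one synthetic chromosome, cycling through a
#' battery of scenarios so that each activity call (active / low / inactive)
#' and each exclusion rule (TSS crowding within 1 kb, CAGE-cluster span over
#' 1 kb, mixed strands, multiple genes) fires at least once when
#' `n_genes >= 8`. Ground-truth labels are recorded per gene and per TSS.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed RNG seed (affects peak heights only; layout is deterministic).
#' @param n_experiments Number of synthetic ChIP-seq experiments whose peak
#'   files are generated near the active TSSs.
#' @return A list with tibbles `tss` (chrom, pos, strand, gene_id),
#'   `robust_peaks`, `permissive_peaks` (chrom, start, end), `gene_spans`
#'   (chrom, start, end, gene_id), a named list `peak_sets` of per-experiment
#'   peak tables, and `truth` (per-gene tibble: gene_id, scenario,
#'   activity, refseq_excluded, cage_exclusion).
#' @export
make_toy_genome <- function(n_genes, seed = 1L, n_experiments = 3L) {
  stopifnot(n_genes >= 1)
  tile <- 100000L
  chrom <- "chrS"
  tss <- list()
  robust <- list()
  permissive <- list()
  truth <- list()
  for (g in seq_len(n_genes)) {
    b <- (g - 1L) * tile + 10000L
    sc <- toy_scenarios[((g - 1L) %% length(toy_scenarios)) + 1L]
    gene <- sprintf("gene%03d", g)
    add_tss <- function(pos, strand = "+", gene_id = gene) {
      tibble(chrom = chrom, pos = pos, strand = strand, gene_id = gene_id)
    }
    peak_at <- function(pos) tibble(chrom = chrom, start = pos - 10L, end = pos + 10L)
    activity <- NA_character_
    refseq_excluded <- FALSE
    cage_exclusion <- "none"
    if (sc == "active_isolated") {
      tss[[g]] <- add_tss(b)
      robust[[length(robust) + 1L]] <- peak_at(b + 100L)
      permissive[[length(permissive) + 1L]] <- peak_at(b + 100L)
      activity <- "active"
    } else if (sc == "low_isolated") {
      tss[[g]] <- add_tss(b)
      permissive[[length(permissive) + 1L]] <- peak_at(b - 50L)
      activity <- "low"
    } else if (sc == "inactive_isolated") {
      tss[[g]] <- add_tss(b)
      activity <- "inactive"
    } else if (sc == "crowded_pair") {
      # two TSSs 800 bp apart: both dropped by the RefSeq 1 kb isolation rule
      tss[[g]] <- bind_rows(add_tss(b), add_tss(b + 800L))
      robust[[length(robust) + 1L]] <- peak_at(b + 50L)
      permissive[[length(permissive) + 1L]] <- peak_at(b + 50L)
      activity <- "active"
      refseq_excluded <- TRUE
    } else if (sc == "cage_run") {
      # gaps of 190 bp chain into one cluster of span 380, retained
      tss[[g]] <- bind_rows(add_tss(b), add_tss(b + 190L), add_tss(b + 380L))
      robust[[length(robust) + 1L]] <- peak_at(b + 200L)
      permissive[[length(permissive) + 1L]] <- peak_at(b + 200L)
      activity <- "active"
      refseq_excluded <- TRUE
    } else if (sc == "mixed_strand") {
      tss[[g]] <- bind_rows(add_tss(b, "+"), add_tss(b + 150L, "-"))
      activity <- "inactive"
      refseq_excluded <- TRUE
      cage_exclusion <- "mixed_strand"
    } else if (sc == "long_chain") {
      # 7 TSSs at 190 bp steps span 1140 bp > 1000 -> excluded
      tss[[g]] <- bind_rows(lapply(0:6, function(i) add_tss(b + i * 190L)))
      activity <- "inactive"
      refseq_excluded <- TRUE
      cage_exclusion <- "span"
    } else if (sc == "multi_gene") {
      tss[[g]] <- bind_rows(add_tss(b, gene_id = gene),
                            add_tss(b + 150L, gene_id = paste0(gene, "b")))
      activity <- "inactive"
      refseq_excluded <- TRUE
      cage_exclusion <- "multi_gene"
    }
    truth[[g]] <- tibble(gene_id = gene, scenario = sc, activity = activity,
                         refseq_excluded = refseq_excluded,
                         cage_exclusion = cage_exclusion)
  }
  tss <- bind_rows(tss)
  truth <- bind_rows(truth)
  gene_spans <- tss |>
    group_by(.data$gene_id) |>
    summarise(chrom = chrom[1], start = min(.data$pos) - 2000L,
              end = max(.data$pos) + 2000L, .groups = "drop") |>
    select("chrom", "start", "end", "gene_id")
  empty_peaks <- tibble(chrom = character(), start = integer(), end = integer())
  robust <- if (length(robust)) bind_rows(robust) else empty_peaks
  permissive <- if (length(permissive)) bind_rows(permissive) else empty_peaks
  active_pos <- tss$pos[tss$gene_id %in% truth$gene_id[truth$activity == "active"]]
  peak_sets <- with_seed(substream_seed(seed, "toy_genome_peaks"), {
    sets <- lapply(seq_len(n_experiments), function(e) {
      if (length(active_pos) == 0L) {
        return(tibble(chrom = character(), start = integer(), end = integer(),
                      summit = integer(), height = numeric()))
      }
      offs <- as.integer(round(stats::runif(length(active_pos), -200, 200)))
      tibble(chrom = chrom,
             start = active_pos + offs - 150L,
             end = active_pos + offs + 150L,
             summit = active_pos + offs,
             height = stats::rgamma(length(active_pos), shape = 4, scale = 5))
    })
    stats::setNames(sets, sprintf("chip%02d", seq_len(n_experiments)))
  })
  list(tss = tss, robust_peaks = robust, permissive_peaks = permissive,
       gene_spans = gene_spans, peak_sets = peak_sets, truth = truth)
}

#' Generate expression driven linearly by a subset of tracks
#'
#' `expression[j] = sum_i weights[i] * matrix[predictors[i], j] + N(0,
#' noise_sd)`. The true predictor set and weights are recorded so feature
#' selection can be scored.
#'
#' @param matrix A [signal_matrix()] (or plain matrix), experiments x
#'   promoters.
#' @param true_predictors Integer row indices of the driving experiments.
#' @param weights Numeric coefficients, one per predictor.
#' @param noise_sd SD of additive Gaussian noise.
#' @param seed RNG seed.
#' @return A list with `expression` (named numeric vector over promoters) and
#'   `truth` (`predictors`, `weights`).
#' @export
make_expression <- function(matrix, true_predictors, weights,
                            noise_sd = 0.1, seed = 1L) {
  if (length(true_predictors) != length(weights)) {
    abort("weights must have one entry per predictor")
  }
  if (any(true_predictors < 1) || any(true_predictors > nrow(matrix))) {
    abort("true_predictors must be valid row indices")
  }
  base <- as.numeric(crossprod(matrix[true_predictors, , drop = FALSE], weights))
  expr <- with_seed(substream_seed(seed, "expression"), {
    base + if (noise_sd > 0) stats::rnorm(ncol(matrix), 0, noise_sd) else 0
  })
  names(expr) <- colnames(matrix)
  list(expression = expr,
       truth = list(predictors = true_predictors, weights = weights))
}

#' Generate promoter-anchored loops, enhancer segments and coverage tracks
#'
#' Each loop gets one anchor overlapping a (randomly chosen) promoter and a
#' remote anchor far away. Remote anchors are assigned an enhancer class --
#' overlapping a strong segment, a weak segment, or nothing -- in exact
#' proportions given by `enhancer_fraction`; strong remotes also carry an
#' overlapping weak segment so that the strong-over-weak precedence is
#' exercised. Per-remote H3K27ac mean levels and a CTCF coverage track with a
#' single known argmax position are generated, so loop selection and
#' re-centering can be checked against ground truth.
#'
#' @param promoters Tibble with columns `id`, `chrom`, `start`, `end`.
#' @param n_loops Number of loops (>= 1).
#' @param enhancer_fraction Numeric length-3 vector `(strong, weak, none)`
#'   summing to 1.
#' @param seed RNG seed.
#' @return A list with tibbles `loops` (BEDPE-like), `enhancers` (BED with
#'   `state`), `h3k27ac` and `ctcf` (bedGraph-like chrom/start/end/value), and
#'   `truth` (per-loop tibble: loop id, promoter id, enhancer class, remote
#'   H3K27ac mean, CTCF argmax center; plus per-promoter selected loop).
#' @export
make_loops <- function(promoters, n_loops, enhancer_fraction = c(0.5, 0.3, 0.2),
                       seed = 1L) {
  promoters <- as_tibble(promoters)
  if (nrow(promoters) == 0L) abort("promoter list is empty")
  stopifnot(n_loops >= 1, length(enhancer_fraction) == 3,
            abs(sum(enhancer_fraction) - 1) < 1e-8)
  # exact class allocation: largest-remainder rounding, then seeded shuffle
  counts <- floor(enhancer_fraction * n_loops)
  rem <- n_loops - sum(counts)
  if (rem > 0) {
    frac <- enhancer_fraction * n_loops - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  classes <- rep(c("strong", "weak", "none"), counts)
  out <- with_seed(substream_seed(seed, "loops"), {
    classes <- sample(classes)
    prom_idx <- sample(nrow(promoters), n_loops, replace = TRUE)
    remote_base <- 5e6 + (seq_len(n_loops) - 1L) * 20000L
    remote_w <- as.integer(round(stats::runif(n_loops, 600, 1400)))
    h3_level <- round(stats::runif(n_loops, 1, 10), 3)
    ctcf_peak <- remote_base + as.integer(round(stats::runif(n_loops, 100, remote_w - 100)))
    list(classes = classes, prom_idx = prom_idx, remote_base = remote_base,
         remote_w = remote_w, h3_level = h3_level, ctcf_peak = ctcf_peak)
  })
  pr <- promoters[out$prom_idx, ]
  loops <- tibble(
    id = sprintf("loop%04d", seq_len(n_loops)),
    chromA = pr$chrom, startA = pr$start, endA = pr$end,
    chromB = pr$chrom, startB = out$remote_base,
    endB = out$remote_base + out$remote_w
  )
  enh <- list()
  for (i in seq_len(n_loops)) {
    s <- out$remote_base[i]
    e <- s + out$remote_w[i]
    if (out$classes[i] == "strong") {
      enh[[length(enh) + 1L]] <- tibble(chrom = pr$chrom[i], start = s + 50L,
                                        end = s + 250L, state = "strong")
      enh[[length(enh) + 1L]] <- tibble(chrom = pr$chrom[i], start = s + 300L,
                                        end = s + 450L, state = "weak")
    } else if (out$classes[i] == "weak") {
      enh[[length(enh) + 1L]] <- tibble(chrom = pr$chrom[i], start = s + 50L,
                                        end = s + 250L, state = "weak")
    }
  }
  enhancers <- if (length(enh)) bind_rows(enh) else
    tibble(chrom = character(), start = integer(), end = integer(), state = character())
  h3k27ac <- tibble(chrom = loops$chromB, start = loops$startB, end = loops$endB,
                    value = out$h3_level)
  ctcf <- bind_rows(
    tibble(chrom = loops$chromB, start = loops$startB, end = loops$endB, value = 1),
    tibble(chrom = loops$chromB, start = out$ctcf_peak,
           end = out$ctcf_peak + 1L, value = 50)
  ) |> arrange(.data$chrom, .data$start)
  loop_truth <- tibble(
    loop_id = loops$id,
    promoter_id = pr$id,
    enhancer_class = out$classes,
    h3k27ac_mean = out$h3_level,
    ctcf_center = out$ctcf_peak
  )
  selected <- loop_truth |>
    group_by(.data$promoter_id) |>
    filter(.data$h3k27ac_mean == max(.data$h3k27ac_mean)) |>
    slice(1) |>
    ungroup() |>
    select(promoter_id = "promoter_id", selected_loop = "loop_id")
  list(loops = loops, enhancers = enhancers, h3k27ac = h3k27ac, ctcf = ctcf,
       truth = list(loops = loop_truth, selected = selected))
}
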