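#' Remove TSSs with a close neighbor
#'
#' Drops every TSS that has another TSS within `isolation_dist` bp on the same
#' chromosome (any strand, any gene): all members of a violating pair or group
#' are removed, keeping only promoters whose 1 kb neighborhood is unambiguous.
#'
#' @param tss Tibble with columns `chrom`, `pos` (and any others, carried
#'   through).
#' @param isolation_dist Maximum crowding distance in bp (default 1000).
#' @return The retained rows of `tss`.
#' @export
filter_isolated_tss <- function(tss, isolation_dist = 1000) {
  tss <- as_tibble(tss)
  if (nrow(tss) == 0L) return(tss)
  keep <- unlist(lapply(split(seq_len(nrow(tss)), tss$chrom), function(idx) {
    pos <- tss$pos[idx]
    ord <- order(pos)
    p <- pos[ord]
    n <- length(p)
    crowded <- logical(n)
    if (n > 1) {
      d <- diff(p)
      hit <- d <= isolation_dist
      crowded[-n] <- crowded[-n] | hit
      crowded[-1] <- crowded[-1] | hit
    }
    idx[ord][!crowded]
  }))
  tss[sort(keep), ]
}

#' Call the activity status of a TSS from tiered CAGE peaks
#'
#' A TSS (or an extended TSS-cluster region) is `active` when at least one
#' robust CAGE peak overlaps its window, `inactive` when not even a permissive
#' peak does, and `low` otherwise (CAGE signal present but below the robust
#' tier). The window is `[start - activity_window, end + activity_window)`;
#' for a single TSS pass `start = end = pos`.
#'
#' @param chrom,start,end Region to test (single values; `start == end` for a
#'   point TSS).
#' @param strand Region strand; used only when `strand_specific = TRUE`.
#' @param robust_peaks,permissive_peaks Tibbles with `chrom`, `start`, `end`
#'   (and optionally `strand`). The robust tier must be a subset of the
#'   permissive tier.
#' @param activity_window Extension in bp on each side (default 500).
#' @param strand_specific If TRUE only peaks on the region's strand count
#'   (used by the CAGE-cluster pipeline).
#' @return One of `"active"`, `"low"`, `"inactive"`.
#' @export
call_activity <- function(chrom, start, end = start, strand = "+",
                          robust_peaks, permissive_peaks,
                          activity_window = 500, strand_specific = FALSE) {
  win_s <- start - activity_window
  win_e <- end + activity_window
  hit <- function(peaks) {
    if (nrow(peaks) == 0L) return(FALSE)
    ok <- peaks$chrom == chrom & peaks$end > win_s & peaks$start < win_e
    if (strand_specific && "strand" %in% names(peaks)) {
      ok <- ok & peaks$strand == strand
    }
    any(ok)
  }
  if (hit(robust_peaks)) return("active")
  if (hit(permissive_peaks)) return("low")
  "inactive"
}

#' Cluster CAGE TSSs into promoter regions
#'
#' Single-linkage chaining: consecutive same-chromosome TSSs closer than
#' `merge_gap` bp join one cluster. Clusters spanning more than `max_span` bp,
#' containing TSSs on both strands, or containing TSSs of more than one gene
#' are flagged excluded (with the reason) rather than dropped; activity is
#' then assigned per retained cluster on its region extended by
#' `activity_window` bp on each side, strand-specifically.
#'
#' @param tss Tibble with `chrom`, `pos`, `strand`, `gene_id`.
#' @param robust_peaks,permissive_peaks Tiered CAGE peak tibbles (see
#'   [call_activity()]); pass `NULL` to skip activity calling.
#' @param merge_gap Chaining distance in bp; gaps strictly smaller join
#'   (default 200).
#' @param max_span Maximum retained cluster span in bp (default 1000).
#' @param activity_window Extension for activity calling (default 500).
#' @return A tibble of TSS clusters: `cluster_id`, `chrom`, `start`, `end`,
#'   `span`, `strand`, `gene_id`, `n_tss`, `status` (active / low / inactive /
#'   excluded), `exclusion_reason` (none / span / mixed_strand / multi_gene),
#'   and a list-column `members` of member positions.
#' @export
cluster_cage_tss <- function(tss, robust_peaks = NULL, permissive_peaks = NULL,
                             merge_gap = 200, max_span = 1000,
                             activity_window = 500) {
  tss <- as_tibble(tss) |> arrange(.data$chrom, .data$pos)
  if (nrow(tss) == 0L) {
    return(tibble(cluster_id = character(), chrom = character(),
                  start = integer(), end = integer(), span = integer(),
                  strand = character(), gene_id = character(),
                  n_tss = integer(), status = character(),
                  exclusion_reason = character(), members = list()))
  }
  new_cluster <- c(TRUE, diff(tss$pos) >= merge_gap |
                     tss$chrom[-1] != tss$chrom[-nrow(tss)])
  cl <- cumsum(new_cluster)
  out <- tss |>
    mutate(.cl = cl) |>
    group_by(.data$.cl) |>
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$pos),
      end = max(.data$pos),
      mixed_strand = length(unique(.data$strand)) > 1L,
      multi_gene = length(unique(.data$gene_id)) > 1L || anyNA(.data$gene_id),
      strand = if (.data$mixed_strand[1]) "*" else .data$strand[1],
      gene_id = if (.data$multi_gene[1]) NA_character_ else .data$gene_id[1],
      n_tss = dplyr::n(),
      members = list(.data$pos),
      .groups = "drop"
    ) |>
    mutate(
      span = .data$end - .data$start,
      exclusion_reason = dplyr::case_when(
        .data$span > max_span ~ "span",
        .data$mixed_strand ~ "mixed_strand",
        .data$multi_gene ~ "multi_gene",
        TRUE ~ "none"
      ),
      cluster_id = sprintf("tc%05d", dplyr::row_number())
    )
  status <- vapply(seq_len(nrow(out)), function(i) {
    if (out$exclusion_reason[i] != "none") return("excluded")
    if (is.null(robust_peaks)) return(NA_character_)
    call_activity(out$chrom[i], out$start[i], out$end[i], out$strand[i],
                  robust_peaks, permissive_peaks,
                  activity_window = activity_window, strand_specific = TRUE)
  }, character(1))
  out |>
    mutate(status = status) |>
    select("cluster_id", "chrom", "start", "end", "span", "strand", "gene_id",
           "n_tss", "status", "exclusion_reason", "members")
}

#' Drop signal-less inactive promoters and collapse duplicate columns
#'
#' Two reductions of the occupancy matrix: (1) inactive promoters whose
#' column is all zeros (no ChIP-seq signal anywhere in the TSS window) are
#' dropped; (2) within a TSS cluster, promoters with exactly identical signal
#' columns collapse to one (the first by coordinate), since very close TSSs
#' see the same peaks.
#'
#' @param matrix A [signal_matrix()] whose columns are promoters.
#' @param promoter_info Tibble with columns `id` (matching matrix columns),
#'   `status`, optionally `cluster_id` and `pos` (needed for the duplicate
#'   collapse).
#' @return The reduced [signal_matrix()].
#' @export
reduce_inactive <- function(matrix, promoter_info) {
  info <- as_tibble(promoter_info)
  stopifnot(all(colnames(matrix) %in% info$id))
  info <- info[match(colnames(matrix), info$id), ]
  drop <- info$status == "inactive" & colSums(abs(matrix)) == 0
  keep <- !drop
  if ("cluster_id" %in% names(info)) {
    ord <- order(if ("pos" %in% names(info)) info$pos else seq_len(nrow(info)))
    seen <- character(0)
    dup <- logical(nrow(info))
    for (j in ord) {
      if (!keep[j]) next
      key <- paste0(info$cluster_id[j], "|",
                    paste(format(matrix[, j], digits = 15), collapse = ","))
      if (key %in% seen) dup[j] <- TRUE else seen <- c(seen, key)
    }
    keep <- keep & !dup
  }
  matrix[, keep, drop = FALSE]
}

#' Full RefSeq-style promoter pipeline
#'
#' Applies the 1 kb isolation filter to annotated TSSs, then calls activity in
#' the `+/- activity_window` around each retained TSS (strand-agnostic), and
#' optionally drops inactive TSSs falling outside every annotated gene span
#' (intergenic).
#'
#' @param tss Tibble with `chrom`, `pos`, `strand`, `gene_id`.
#' @param robust_peaks,permissive_peaks Tiered CAGE peak tibbles.
#' @param gene_spans Optional tibble (`chrom`, `start`, `end`) of gene bodies;
#'   when given, intergenic inactive TSSs are removed.
#' @param isolation_dist,activity_window See [filter_isolated_tss()] and
#'   [call_activity()].
#' @return Tibble of retained promoters with a `status` column.
#' @export
define_promoters_refseq <- function(tss, robust_peaks, permissive_peaks,
                                    gene_spans = NULL, isolation_dist = 1000,
                                    activity_window = 500) {
  kept <- filter_isolated_tss(tss, isolation_dist)
  if (nrow(kept) == 0L) return(mutate(kept, status = character(0)))
  kept$status <- vapply(seq_len(nrow(kept)), function(i) {
    call_activity(kept$chrom[i], kept$pos[i], kept$pos[i], kept$strand[i],
                  robust_peaks, permissive_peaks,
                  activity_window = activity_window, strand_specific = FALSE)
  }, character(1))
  if (!is.null(gene_spans)) {
    genic <- vapply(seq_len(nrow(kept)), function(i) {
      any(gene_spans$chrom == kept$chrom[i] &
            gene_spans$start <= kept$pos[i] &
            gene_spans$end > kept$pos[i])
    }, logical(1))
    kept <- kept[kept$status != "inactive" | genic, ]
  }
  kept
}
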