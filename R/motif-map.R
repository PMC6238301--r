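#' Best motif hit per promoter
#'
#' Per (promoter, motif) group, keeps the hit with the smallest p-value; ties
#' are broken by the position closest to the TSS, then by the leftmost
#' position.
#'
#' @param hits Tibble of motif hits: `promoter_id`, `motif_id`, `position`
#'   (bp relative to the TSS, strand-oriented), `score`, `p_value`.
#' @return One row per (promoter, motif) with the winning hit.
#' @export
best_hit_per_promoter <- function(hits) {
  as_tibble(hits) |>
    group_by(.data$promoter_id, .data$motif_id) |>
    arrange(.data$p_value, abs(.data$position), .data$position,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Motif score matrix in heatmap column order
#'
#' Rows are motifs, columns are promoters in the order of the biclustered
#' heatmap; a missing hit scores 0.
#'
#' @param best_hits Output of [best_hit_per_promoter()].
#' @param motifs Character vector of motif ids (row order).
#' @param col_order Character vector of promoter ids in heatmap order (e.g.
#'   `colnames(X)[order_heatmap(X, cons)$col_order]`).
#' @return A numeric matrix `length(motifs)` x `length(col_order)`.
#' @export
motif_matrix <- function(best_hits, motifs, col_order) {
  best_hits <- as_tibble(best_hits)
  unknown <- setdiff(best_hits$promoter_id, col_order)
  if (length(unknown) > 0) {
    abort(paste0("promoters missing from col_order: ",
                 paste(utils::head(unknown, 3), collapse = ", ")))
  }
  out <- matrix(0, length(motifs), length(col_order),
                dimnames = list(motifs, col_order))
  hit <- filter(best_hits, .data$motif_id %in% motifs)
  if (nrow(hit) > 0) {
    out[cbind(match(hit$motif_id, motifs), match(hit$promoter_id, col_order))] <-
      hit$score
  }
  out
}

#' TSS-relative positions of confident motif hits
#'
#' Restricts best hits to those with `p_value < filter_p` lying within
#' `[-window, window]` of the TSS.
#'
#' @param best_hits Output of [best_hit_per_promoter()].
#' @param window Half-width of the promoter window in bp (default 200).
#' @param filter_p Strict p-value cutoff (default 0.001).
#' @return Tibble `promoter_id`, `motif_id`, `position`, `score`, `p_value`.
#' @export
motif_positions <- function(best_hits, window = 200, filter_p = 0.001) {
  if (window <= 0) abort("window must be positive")
  as_tibble(best_hits) |>
    filter(.data$p_value < filter_p,
           abs(.data$position) <= window) |>
    select("promoter_id", "motif_id", "position", "score", "p_value")
}
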