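#' Categorize promoters for cross-clustering comparison
#'
#' Maps every promoter to a mutually exclusive comparison category:
#' its consensus cluster label when retained, otherwise
#' `"active unassigned"` / `"inactive unassigned"` by activity status,
#' `"low"` when the CAGE signal is positive but below the robust tier, and
#' `"intergenic"` when its matrix column carries no ChIP-seq signal at all.
#' When several apply, precedence is intergenic > low > unassigned > cluster.
#'
#' @param promoters Tibble with columns `id` and `status` (active / inactive
#'   / low).
#' @param consensus A `consensus_solution` over the same promoters.
#' @param X The [signal_matrix()] the consensus was computed on.
#' @return A tibble `id`, `category`.
#' @export
categorize <- function(promoters, consensus, X) {
  promoters <- as_tibble(promoters)
  if (!all(promoters$id %in% colnames(X))) abort("unknown promoter id")
  zero_col <- colSums(abs(unclass(as.matrix(X)))) == 0
  cluster_of <- stats::setNames(
    as.character(consensus$retained_cols$cluster),
    consensus$retained_cols$id
  )
  category <- vapply(seq_len(nrow(promoters)), function(i) {
    id <- promoters$id[i]
    if (zero_col[[id]]) return("intergenic")
    if (promoters$status[i] == "low") return("low")
    cl <- cluster_of[id]
    if (!is.na(cl)) return(paste0("cluster ", cl))
    paste0(promoters$status[i], " unassigned")
  }, character(1))
  tibble(id = promoters$id, category = category)
}

#' Cross-tabulate two categorizations of the same promoters
#'
#' @param cat_a,cat_b Tibbles `id`, `category` over the same promoter
#'   universe (e.g. two cell lines, or two clustering algorithms).
#' @return A tibble in long form: `category_a`, `category_b`, `n`; the counts
#'   sum to the universe size.
#' @export
cross_tabulate <- function(cat_a, cat_b) {
  cat_a <- as_tibble(cat_a)
  cat_b <- as_tibble(cat_b)
  if (!setequal(cat_a$id, cat_b$id) || nrow(cat_a) != nrow(cat_b)) {
    abort("categorizations cover different promoter universes")
  }
  dplyr::inner_join(
    select(cat_a, "id", category_a = "category"),
    select(cat_b, "id", category_b = "category"),
    by = "id"
  ) |>
    dplyr::count(.data$category_a, .data$category_b, name = "n")
}

#' Wide confusion table from a long cross-tabulation
#'
#' @param xtab Output of [cross_tabulate()].
#' @return A tibble with `category_a` rows and one column per `category_b`
#'   level (zero-filled).
#' @export
comparison_table <- function(xtab) {
  tidyr::pivot_wider(xtab, names_from = "category_b", values_from = "n",
                     values_fill = 0L)
}
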