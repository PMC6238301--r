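#' Confusion matrix between two column clusterings
#'
#' Entry (a, b) counts the columns assigned to cluster `a` of `sol_a` and to
#' cluster `b` of `sol_b`; unassigned columns contribute nowhere.
#'
#' @param sol_a,sol_b `bicluster_solution` objects over the same column
#'   universe.
#' @return An integer matrix, clusters of `sol_a` x clusters of `sol_b`.
#' @export
confusion_matrix <- function(sol_a, sol_b) {
  if (sol_a$n_cols != sol_b$n_cols) abort("solutions cover different column universes")
  ka <- length(sol_a$biclusters)
  kb <- length(sol_b$biclusters)
  out <- matrix(0L, ka, kb)
  for (a in seq_len(ka)) {
    for (b in seq_len(kb)) {
      out[a, b] <- length(intersect(sol_a$biclusters[[a]]$cols,
                                    sol_b$biclusters[[b]]$cols))
    }
  }
  out
}

#' Optimal cluster assignment by linear assignment
#'
#' Solves the (rectangular) linear assignment problem on a confusion matrix:
#' a one-to-one partial map from source clusters (rows) to target clusters
#' (columns) maximizing the total matched overlap. Surplus clusters on the
#' larger side stay unmapped. Ties between equally good assignments are
#' broken deterministically (lexicographically smallest assignment vector).
#'
#' @param confusion Non-negative numeric matrix of overlap counts.
#' @return A list with `assignment` (integer vector: target cluster per
#'   source cluster, `NA` if unmapped) and `total_overlap`.
#' @export
assign_clusters <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) abort("confusion counts must be non-negative")
  ka <- nrow(confusion)
  kb <- ncol(confusion)
  if (ka == 0L || kb == 0L) {
    return(list(assignment = rep(NA_integer_, ka), total_overlap = 0))
  }
  # maximum-weight bipartite matching; a tiny lexicographic perturbation makes
  # the optimum unique so ties break toward smaller (source, target) pairs
  eps <- 1 / (4 * (ka + 1) * (kb + 1) * (ka * kb + 1))
  pert <- outer(seq_len(ka), seq_len(kb), function(i, j) {
    eps * (1 - (i - 1) / ka - (j - 1) / (ka * kb))
  })
  w <- confusion + pert
  edges <- expand.grid(a = seq_len(ka), b = seq_len(kb))
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, ka), rep(TRUE, kb)),
    edges = as.vector(rbind(edges$a, ka + edges$b))
  )
  mm <- igraph::max_bipartite_match(g, weights = w[cbind(edges$a, edges$b)])
  assignment <- mm$matching[seq_len(ka)] - ka
  assignment[is.na(assignment) | assignment < 1] <- NA_integer_
  total <- sum(confusion[cbind(seq_len(ka), assignment)], na.rm = TRUE)
  list(assignment = as.integer(assignment), total_overlap = total)
}

#' Robust consensus biclustering
#'
#' The consensus procedure over repeated randomized base runs:
#' \enumerate{
#'   \item run the base engine `n_runs` times with derived seeds;
#'   \item take the run with the largest number of column clusters as the
#'     *target clustering* (ties broken randomly, driven by the seed);
#'   \item map every run's clusters onto the target by solving the linear
#'     assignment problem on their confusion matrix ([assign_clusters()]);
#'   \item per column, tally the frequency (over all `n_runs` runs, the
#'     target mapping to itself) with which it lands in each target cluster;
#'     keep columns whose best frequency exceeds `min_freq`;
#'   \item keep rows associated to one target cluster in more than half of
#'     the runs, assigned to their most frequent cluster;
#'   \item compute, for every retained row and column cluster, the Welch
#'     t-test comparing the row's values inside versus outside the cluster
#'     (the `-log10 p` bar heights of the heatmap annotation).
#' }
#'
#' @param X A [signal_matrix()] or numeric matrix.
#' @param engine `"ssvd"` or `"kmeans"`.
#' @param n_runs Number of base runs (>= 2).
#' @param min_freq Column retention threshold (strict; default 0.5).
#' @param seed RNG seed controlling run seeds and the target tie-break.
#' @param k Number of clusters for the k-means engine; `"auto"` (default)
#'   selects it once with [choose_k()].
#' @param ... Passed to the base engine ([run_ssvd()] or [kmeans_biclust()]).
#' @return A `consensus_solution` object; see [filter_consensus()],
#'   [tidy.consensus_solution()], [order_heatmap()].
#' @export
consensus_biclust <- function(X, engine = c("ssvd", "kmeans"), n_runs = 20L,
                              min_freq = 0.5, seed = 1L, k = "auto", ...) {
  engine <- match.arg(engine)
  stopifnot(n_runs >= 2)
  X0 <- unclass(as.matrix(X))
  run_seeds <- with_seed(substream_seed(seed, "run_seeds"),
                         sample.int(2147483587L, n_runs))
  if (engine == "kmeans" && identical(k, "auto")) {
    k <- choose_k(X0, k_range = 2:min(8L, ncol(X0) - 1L),
                  seed = substream_seed(seed, "choose_k"))
  }
  runs <- lapply(run_seeds, function(s) {
    if (engine == "ssvd") {
      run_ssvd(X0, seed = s, ...)
    } else {
      kmeans_biclust(X0, k = k, seed = s, ...)
    }
  })
  n_clusters <- vapply(runs, function(r) length(r$biclusters), integer(1))
  if (all(n_clusters == 0L)) {
    return(new_consensus_solution(NULL, NULL, NULL, NULL, NULL,
                                  n_runs, min_freq, seed, X0, engine))
  }
  target_idx <- with_seed(substream_seed(seed, "target_tiebreak"), {
    best <- which(n_clusters == max(n_clusters))
    if (length(best) > 1L) sample(best, 1L) else best
  })
  target <- runs[[target_idx]]
  kt <- length(target$biclusters)
  # votes[col, target_cluster] and row_votes[row, target_cluster]
  votes <- matrix(0L, ncol(X0), kt)
  row_votes <- matrix(0L, nrow(X0), kt)
  for (r in runs) {
    map <- assign_clusters(confusion_matrix(r, target))$assignment
    for (a in seq_along(r$biclusters)) {
      t_cl <- map[a]
      if (is.na(t_cl)) next
      cols <- r$biclusters[[a]]$cols
      votes[cols, t_cl] <- votes[cols, t_cl] + 1L
      rows <- r$biclusters[[a]]$rows
      row_votes[rows, t_cl] <- row_votes[rows, t_cl] + 1L
    }
  }
  col_freq <- votes / n_runs
  best_freq <- apply(col_freq, 1, max)
  best_cluster <- apply(col_freq, 1, which.max)
  retained_cols <- tibble(
    index = which(best_freq > min_freq),
    id = colnames(X0)[which(best_freq > min_freq)] %||%
      as.character(which(best_freq > min_freq)),
    cluster = best_cluster[best_freq > min_freq],
    frequency = best_freq[best_freq > min_freq]
  )
  row_best <- apply(row_votes, 1, max)
  row_cluster <- apply(row_votes, 1, which.max)
  retained_rows <- tibble(
    index = which(row_best > n_runs / 2),
    id = rownames(X0)[which(row_best > n_runs / 2)] %||%
      as.character(which(row_best > n_runs / 2)),
    cluster = row_cluster[row_best > n_runs / 2],
    frequency = row_best[row_best > n_runs / 2] / n_runs
  )
  row_tests <- compute_row_tests(X0, retained_rows$index, retained_cols)
  new_consensus_solution(target, col_freq, retained_cols, retained_rows,
                         row_tests, n_runs, min_freq, seed, X0, engine)
}

compute_row_tests <- function(X, row_idx, retained_cols) {
  clusters <- sort(unique(retained_cols$cluster))
  if (length(row_idx) == 0L || length(clusters) == 0L) {
    return(tibble(row_index = integer(), row_id = character(),
                  cluster = integer(), t = numeric(), p = numeric(),
                  neglog10p = numeric()))
  }
  purrr::map_dfr(clusters, function(cl) {
    inside <- retained_cols$index[retained_cols$cluster == cl]
    if (length(inside) == 0L || length(inside) >= ncol(X)) return(NULL)
    purrr::map_dfr(row_idx, function(r) {
      wt <- welch_test(X[r, inside], X[r, -inside])
      tibble(row_index = r,
             row_id = rownames(X)[r] %||% as.character(r),
             cluster = cl, t = wt$t, p = wt$p, neglog10p = wt$neglog10p)
    })
  })
}

new_consensus_solution <- function(target, col_freq, retained_cols,
                                   retained_rows, row_tests, n_runs, min_freq,
                                   seed, X, engine) {
  empty_cols <- tibble(index = integer(), id = character(),
                       cluster = integer(), frequency = numeric())
  structure(list(
    target = target,
    column_frequency = col_freq,
    retained_cols = retained_cols %||% empty_cols,
    retained_rows = retained_rows %||% empty_cols,
    row_tests = row_tests %||% tibble(),
    n_runs = n_runs, min_freq = min_freq, seed = seed, engine = engine,
    n_cols = ncol(X), n_rows = nrow(X),
    col_ids = colnames(X) %||% as.character(seq_len(ncol(X))),
    row_ids = rownames(X) %||% as.character(seq_len(nrow(X)))
  ), class = "consensus_solution")
}

#' @export
print.consensus_solution <- function(x, ...) {
  kt <- if (is.null(x$target)) 0L else length(x$target$biclusters)
  cat(sprintf(paste0("<consensus_solution> engine=%s, %d runs, %d target ",
                     "cluster(s)\n  retained: %d/%d columns, %d/%d rows ",
                     "(min_freq %.2f)\n"),
              x$engine, x$n_runs, kt, nrow(x$retained_cols), x$n_cols,
              nrow(x$retained_rows), x$n_rows, x$min_freq))
  invisible(x)
}

#' Re-apply the column frequency filter at a different threshold
#'
#' The consensus frequencies are computed once; retention at a new `min_freq`
#' is a pure filter, so raising the threshold can only shrink the retained
#' column set.
#'
#' @param consensus A `consensus_solution`.
#' @param min_freq New strict retention threshold.
#' @return The `consensus_solution` with `retained_cols`, `row_tests` and
#'   `min_freq` updated.
#' @export
filter_consensus <- function(consensus, min_freq) {
  if (is.null(consensus$column_frequency)) return(consensus)
  cf <- consensus$column_frequency
  best_freq <- apply(cf, 1, max)
  best_cluster <- apply(cf, 1, which.max)
  keep <- which(best_freq > min_freq)
  consensus$retained_cols <- tibble(
    index = keep, id = consensus$col_ids[keep],
    cluster = best_cluster[keep], frequency = best_freq[keep]
  )
  consensus$min_freq <- min_freq
  consensus
}

#' Welch t-test of a row against a column cluster
#'
#' Compares the mean of a matrix row over the columns inside a cluster with
#' its mean outside; the `-log10 p` is the bar height drawn next to ordered
#' heatmaps.
#'
#' @param X Matrix (experiments x promoters).
#' @param col_cluster Integer column indices, a non-empty proper subset.
#' @param row Row index.
#' @return A one-row tibble `t`, `p`, `neglog10p`.
#' @export
row_cluster_ttest <- function(X, col_cluster, row) {
  X <- unclass(as.matrix(X))
  if (length(col_cluster) == 0L || length(col_cluster) >= ncol(X)) {
    abort("col_cluster must be a non-empty proper subset of the columns")
  }
  welch_test(X[row, col_cluster], X[row, -col_cluster])
}

#' Heatmap ordering induced by a consensus solution
#'
#' Columns are grouped by assigned cluster (clusters ordered by size,
#' descending) and sorted within a cluster by mean signal over the cluster's
#' associated rows (falling back to all rows), descending; unassigned columns
#' come last. Rows are grouped by associated cluster in the same cluster
#' order and sorted by their mean over the cluster's columns; unassociated
#' rows come last.
#'
#' @param X A [signal_matrix()] or numeric matrix.
#' @param consensus A `consensus_solution` over `X`.
#' @return A list with `row_order`, `col_order` (integer permutations),
#'   `col_boundaries`, `row_boundaries` (cumulative cluster sizes, for
#'   drawing separators), and `col_clusters`/`row_clusters` (cluster label
#'   per ordered column/row, `NA` for unassigned).
#' @export
order_heatmap <- function(X, consensus) {
  X <- unclass(as.matrix(X))
  rc <- consensus$retained_cols
  rr <- consensus$retained_rows
  sizes <- table(factor(rc$cluster))
  cluster_order <- as.integer(names(sort(sizes, decreasing = TRUE)))
  col_order <- integer(0)
  col_clusters <- integer(0)
  col_boundaries <- integer(0)
  for (cl in cluster_order) {
    cols <- rc$index[rc$cluster == cl]
    rows_cl <- rr$index[rr$cluster == cl]
    key_rows <- if (length(rows_cl) > 0) rows_cl else seq_len(nrow(X))
    ms <- colMeans(X[key_rows, cols, drop = FALSE])
    cols <- cols[order(-ms, cols)]
    col_order <- c(col_order, cols)
    col_clusters <- c(col_clusters, rep(cl, length(cols)))
    col_boundaries <- c(col_boundaries, length(col_order))
  }
  rest <- setdiff(seq_len(ncol(X)), col_order)
  col_order <- c(col_order, rest)
  col_clusters <- c(col_clusters, rep(NA_integer_, length(rest)))
  row_order <- integer(0)
  row_clusters <- integer(0)
  row_boundaries <- integer(0)
  for (cl in cluster_order) {
    rows <- rr$index[rr$cluster == cl]
    if (length(rows) == 0L) next
    cols_cl <- rc$index[rc$cluster == cl]
    key_cols <- if (length(cols_cl) > 0) cols_cl else seq_len(ncol(X))
    ms <- rowMeans(X[rows, key_cols, drop = FALSE])
    rows <- rows[order(-ms, rows)]
    row_order <- c(row_order, rows)
    row_clusters <- c(row_clusters, rep(cl, length(rows)))
    row_boundaries <- c(row_boundaries, length(row_order))
  }
  rest_r <- setdiff(seq_len(nrow(X)), row_order)
  row_order <- c(row_order, rest_r)
  row_clusters <- c(row_clusters, rep(NA_integer_, length(rest_r)))
  list(row_order = row_order, col_order = col_order,
       col_boundaries = col_boundaries, row_boundaries = row_boundaries,
       col_clusters = col_clusters, row_clusters = row_clusters)
}

#' Tidy a consensus solution
#'
#' @param x A `consensus_solution`.
#' @param ... Unused.
#' @return A tibble of retained indices: `dimension` (row/column), `index`,
#'   `id`, `cluster`, `frequency`.
#' @export
tidy.consensus_solution <- function(x, ...) {
  bind_rows(
    mutate(x$retained_cols, dimension = "column"),
    mutate(x$retained_rows, dimension = "row")
  ) |>
    select("dimension", "index", "id", "cluster", "frequency")
}

#' @export
glance.consensus_solution <- function(x, ...) {
  tibble(
    engine = x$engine, n_runs = x$n_runs, min_freq = x$min_freq,
    n_target_clusters = if (is.null(x$target)) 0L else length(x$target$biclusters),
    n_retained_cols = nrow(x$retained_cols),
    n_retained_rows = nrow(x$retained_rows),
    seed = x$seed
  )
}
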