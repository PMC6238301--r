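# seeded k-means++ initial centers over the rows of `obs`
kmeanspp_centers <- function(obs, k) {
  n <- nrow(obs)
  centers <- matrix(NA_real_, k, ncol(obs))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- obs[idx, ]
  d2 <- colSums((t(obs) - centers[1L, ])^2)
  for (i in seq_len(k - 1L)) {
    if (sum(d2) == 0) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[i + 1L, ] <- obs[idx, ]
    d2 <- pmin(d2, colSums((t(obs) - centers[i + 1L, ])^2))
  }
  centers
}

seeded_kmeans <- function(obs, k, seed) {
  with_seed(seed, {
    centers <- kmeanspp_centers(obs, k)
    centers <- centers[!duplicated(centers), , drop = FALSE]
    if (nrow(centers) < k) {
      # degenerate data with fewer distinct points than k
      extra <- obs[sample.int(nrow(obs), k - nrow(centers)), , drop = FALSE]
      centers <- rbind(centers, extra + stats::rnorm(length(extra), 0, 1e-8))
    }
    suppressWarnings(stats::kmeans(obs, centers = centers, iter.max = 50L))
  })
}

#' Choose the number of column clusters by the elbow rule
#'
#' Runs k-means on the matrix columns for each `k` in `k_range` and returns
#' the smallest `k` whose relative improvement in total within-cluster sum of
#' squares from `k` to `k + 1` falls below `tol` (default 5 percent); when no
#' elbow occurs, the largest `k` is returned. A degenerate matrix whose
#' columns are all identical returns `min(k_range)`.
#'
#' @param X A [signal_matrix()] or numeric matrix (columns are clustered).
#' @param k_range Integer candidates, within `[2, ncol(X) - 1]`.
#' @param seed RNG seed.
#' @param tol Relative SSE-improvement threshold for the elbow.
#' @return The chosen `k`.
#' @export
choose_k <- function(X, k_range = 2:8, seed = 1L, tol = 0.05) {
  X <- unclass(as.matrix(X))
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > ncol(X) - 1) {
    abort("k_range must lie within [2, ncol(X) - 1]")
  }
  obs <- t(X)
  if (all(apply(obs, 2, function(v) length(unique(v)) == 1L)) ||
      nrow(unique(obs)) == 1L) {
    return(min(k_range))
  }
  if (length(k_range) == 1L) return(k_range)
  ks <- c(k_range, max(k_range) + 1L)
  sse <- vapply(seq_along(ks), function(i) {
    seeded_kmeans(obs, ks[i], substream_seed(seed, paste0("choose_k", ks[i])))$tot.withinss
  }, numeric(1))
  for (i in seq_along(k_range)) {
    if (sse[i] <= 0) return(k_range[i])
    if ((sse[i] - sse[i + 1L]) / sse[i] < tol) return(k_range[i])
  }
  max(k_range)
}

#' k-means + t-test biclustering
#'
#' Partitions the matrix columns (promoters) with seeded k-means (k-means++
#' initialization), then associates rows to each column cluster by a
#' two-sided Welch t-test of the row's values inside versus outside the
#' cluster: rows with `p < alpha` join that cluster's row set (a row may join
#' several clusters). Column clusters of size < 2 get an empty row set, as
#' the t-test is undefined there.
#'
#' @param X A [signal_matrix()] or numeric matrix.
#' @param k Number of column clusters (2 <= k <= ncol).
#' @param alpha Row-association p-value threshold (default 0.001).
#' @param seed RNG seed.
#' @return A `bicluster_solution` with `engine = "kmeans_ttest"`; each
#'   bicluster's `score` is the mean signal of its submatrix, and row sets
#'   may overlap across clusters.
#' @export
kmeans_biclust <- function(X, k, alpha = 0.001, seed = 1L) {
  X0 <- unclass(as.matrix(X))
  stopifnot(k >= 2, k <= ncol(X0))
  km <- seeded_kmeans(t(X0), k, substream_seed(seed, "kmeans_biclust"))
  membership <- km$cluster
  biclusters <- lapply(seq_len(k), function(cl) {
    cols <- which(membership == cl)
    if (length(cols) < 2L || length(cols) > ncol(X0) - 2L) {
      rows <- integer(0)
    } else {
      rows <- which(vapply(seq_len(nrow(X0)), function(r) {
        wt <- welch_test(X0[r, cols], X0[r, -cols])
        !is.na(wt$p) && wt$p < alpha
      }, logical(1)))
    }
    score <- if (length(rows) > 0) mean(X0[rows, cols, drop = FALSE]) else 0
    list(rows = rows, cols = cols, score = score)
  })
  sol <- new_bicluster_solution(biclusters, nrow(X0), ncol(X0),
                                "kmeans_ttest", seed,
                                rownames(X0), colnames(X0))
  # every column is assigned by the k-means partition
  sol$unassigned_cols <- integer(0)
  sol
}
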