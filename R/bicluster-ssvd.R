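#' Base biclustering engines
#'
#' Two engines share one output contract (a `bicluster_solution`): a sparse
#' rank-1 SVD layer method with randomized stability selection, and a k-means
#' column clustering with per-row Welch t-test association. Both are seedable
#' and deterministic given the seed, which is what the consensus wrapper
#' (see [consensus_biclust()]) relies on.
#'
#' @name bicluster-engines
NULL

soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

# Sparse rank-1 decomposition by alternating soft-thresholded power
# iterations (SSVD in the style of Lee et al. 2010). For the fixed unit
# vector on the other side, the LS loading estimate z is soft-thresholded;
# the threshold is chosen among candidates spanning `sparsity_grid` support
# sizes by a BIC-like criterion on the optimally rescaled thresholded fit:
# RSS/(npe * sigma2hat) + df * log(npe)/npe, with sigma2hat the residual
# variance of the unpenalized rank-1 fit. Rescaling matters: without it the
# shrinkage cost masks the fit gain of keeping a full block.
sparse_rank1 <- function(X, sparsity_grid = 500L, max_iter = 30L, tol = 1e-6,
                         init_u = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  total <- sum(X^2)
  if (total <= 1e-18) return(NULL)
  if (is.null(init_u)) {
    sv <- svd(X, nu = 1L, nv = 1L)
    u <- sv$u[, 1L]
    v <- sv$v[, 1L] * sv$d[1L]
  } else {
    nrm <- sqrt(sum(init_u^2))
    if (nrm == 0) return(NULL)
    u <- init_u / nrm
    v <- as.numeric(crossprod(X, u))
  }
  npe <- n * p
  pick <- function(z) {
    if (any(!is.finite(z))) return(NULL)
    az <- abs(z)
    nz <- sum(az > 0)
    if (nz == 0L) return(NULL)
    rss0 <- total - sum(z^2)
    sigma2 <- max(rss0 / max(npe - length(z), 1L), 1e-12)
    zs <- sort(az[az > 0], decreasing = TRUE)
    # candidate thresholds between consecutive sorted |z|: support = top-k;
    # closed forms via cumulative sums make the scan O(p log p)
    ks <- if (nz <= sparsity_grid) seq_len(nz) else
      unique(round(seq(1L, nz, length.out = sparsity_grid)))
    lam <- ifelse(ks == nz, 0, (zs[ks] + zs[pmin(ks + 1L, nz)]) / 2)
    cum1 <- cumsum(zs)[ks]
    cum2 <- cumsum(zs^2)[ks]
    vz <- cum2 - lam * cum1                       # <soft(z), z>
    vv <- cum2 - 2 * lam * cum1 + ks * lam^2      # ||soft(z)||^2
    ok <- vv > 0 & vz > 0
    if (!any(ok)) return(NULL)
    rss <- total - vz^2 / vv                      # after optimal rescaling
    bic <- rss / (npe * sigma2) + ks * log(npe) / npe
    bic[!ok] <- Inf
    i <- which.min(bic)
    zt <- soft_threshold(z, lam[i])
    (vz[i] / vv[i]) * zt
  }
  for (it in seq_len(max_iter)) {
    u_old <- u
    v_old <- v
    z <- as.numeric(crossprod(X, u))       # length p, given unit u
    v <- pick(z)
    if (is.null(v)) return(NULL)
    w <- as.numeric(X %*% (v / sqrt(sum(v^2))))
    u_new <- pick(w)
    if (is.null(u_new)) return(NULL)
    u <- u_new / sqrt(sum(u_new^2))
    if (length(u_old) == length(u) &&
        max(abs(u - u_old)) < tol &&
        sqrt(sum((v - v_old)^2)) < tol * max(1, sqrt(sum(v_old^2)))) {
      break
    }
  }
  rows <- which(u != 0)
  cols <- which(v != 0)
  if (length(rows) == 0L || length(cols) == 0L) return(NULL)
  list(rows = rows, cols = cols, u = u, v = v)
}

#' Extract one stable sparse-SVD bicluster layer
#'
#' Runs the sparse rank-1 decomposition on random row/column subsamples of
#' the matrix and keeps the rows and columns selected in at least
#' `stability_threshold` of the subsamples containing them. Returns `NULL`
#' when either support empties (no stable layer left).
#'
#' @param X Numeric matrix (experiments x promoters), finite.
#' @param seed RNG seed for the subsampling.
#' @param subsample_fraction Fraction of rows and of columns per subsample.
#' @param n_subsamples Number of random subsamples.
#' @param stability_threshold Minimum selection frequency to retain an index.
#' @param sparsity_grid Number of candidate support sizes scanned when
#'   choosing the soft-threshold penalty by BIC.
#' @return A list `(rows, cols, score)` or `NULL`; `score` is the leading
#'   singular value of the selected submatrix.
#' @export
ssvd_layer <- function(X, seed = 1L, subsample_fraction = 0.5,
                       n_subsamples = 100L, stability_threshold = 0.6,
                       sparsity_grid = 500L) {
  if (any(!is.finite(X))) abort("matrix must be finite")
  n <- nrow(X)
  p <- ncol(X)
  if (sum(X^2) <= 1e-18) return(NULL)
  full <- sparse_rank1(X, sparsity_grid)
  if (is.null(full)) return(NULL)
  sel_rows <- numeric(n)
  sel_cols <- numeric(p)
  seen_rows <- numeric(n)
  seen_cols <- numeric(p)
  nr <- max(2L, floor(subsample_fraction * n))
  nc <- max(2L, floor(subsample_fraction * p))
  with_seed(seed, {
    for (s in seq_len(n_subsamples)) {
      ri <- sort(sample.int(n, nr))
      ci <- sort(sample.int(p, nc))
      seen_rows[ri] <- seen_rows[ri] + 1
      seen_cols[ci] <- seen_cols[ci] + 1
      # warm-start from the full-matrix layer so every subsample estimates
      # the same rank-1 layer rather than whichever block dominates it
      fit <- sparse_rank1(X[ri, ci, drop = FALSE], sparsity_grid,
                          init_u = full$u[ri])
      if (!is.null(fit)) {
        sel_rows[ri[fit$rows]] <- sel_rows[ri[fit$rows]] + 1
        sel_cols[ci[fit$cols]] <- sel_cols[ci[fit$cols]] + 1
      }
    }
  })
  rows <- which(seen_rows > 0 & sel_rows / pmax(seen_rows, 1) >= stability_threshold)
  cols <- which(seen_cols > 0 & sel_cols / pmax(seen_cols, 1) >= stability_threshold)
  # a stable layer must also be part of the full-matrix fit
  rows <- intersect(rows, full$rows)
  cols <- intersect(cols, full$cols)
  if (length(rows) == 0L || length(cols) == 0L) return(NULL)
  sub <- X[rows, cols, drop = FALSE]
  score <- svd(sub, nu = 0L, nv = 0L)$d[1L]
  list(rows = rows, cols = cols, score = score)
}

new_bicluster_solution <- function(biclusters, n_rows, n_cols, engine, seed,
                                   row_ids = NULL, col_ids = NULL) {
  used_rows <- sort(unique(unlist(lapply(biclusters, `[[`, "rows"))))
  used_cols <- sort(unique(unlist(lapply(biclusters, `[[`, "cols"))))
  structure(list(
    biclusters = biclusters,
    unassigned_rows = setdiff(seq_len(n_rows), used_rows),
    unassigned_cols = setdiff(seq_len(n_cols), used_cols),
    n_rows = n_rows, n_cols = n_cols,
    row_ids = row_ids %||% as.character(seq_len(n_rows)),
    col_ids = col_ids %||% as.character(seq_len(n_cols)),
    engine = engine, seed = seed
  ), class = "bicluster_solution")
}

#' @export
print.bicluster_solution <- function(x, ...) {
  cat(sprintf("<bicluster_solution> engine=%s, %d bicluster(s)\n",
              x$engine, length(x$biclusters)))
  for (i in seq_along(x$biclusters)) {
    b <- x$biclusters[[i]]
    cat(sprintf("  %d: %d rows x %d cols (score %.3g)\n",
                i, length(b$rows), length(b$cols), b$score %||% NA))
  }
  cat(sprintf("  unassigned: %d rows, %d cols\n",
              length(x$unassigned_rows), length(x$unassigned_cols)))
  invisible(x)
}

#' Tidy a bicluster solution
#'
#' @param x A `bicluster_solution`.
#' @param ... Unused.
#' @return A tibble with one row per assigned index: `cluster`, `dimension`
#'   (`"row"` or `"column"`), `index`, `id`.
#' @export
tidy.bicluster_solution <- function(x, ...) {
  purrr::imap_dfr(x$biclusters, function(b, i) {
    bind_rows(
      tibble(cluster = i, dimension = "row", index = b$rows,
             id = x$row_ids[b$rows]),
      tibble(cluster = i, dimension = "column", index = b$cols,
             id = x$col_ids[b$cols])
    )
  })
}

#' @export
glance.bicluster_solution <- function(x, ...) {
  tibble(engine = x$engine, n_biclusters = length(x$biclusters),
         n_assigned_cols = x$n_cols - length(x$unassigned_cols),
         n_assigned_rows = x$n_rows - length(x$unassigned_rows),
         seed = x$seed)
}

# membership vector over columns: integer cluster index, NA if unassigned
column_membership <- function(sol) {
  m <- rep(NA_integer_, sol$n_cols)
  for (i in seq_along(sol$biclusters)) m[sol$biclusters[[i]]$cols] <- i
  m
}

#' Sparse-SVD biclustering by successive stable layers
#'
#' Repeatedly extracts a stable rank-1 layer with [ssvd_layer()] and deflates
#' the matrix by subtracting the rank-1 fit on the layer's support, stopping
#' when no stable layer remains or `max_layers` is reached. Columns (and
#' rows) claimed by several layers are assigned to the layer with the larger
#' mean signal over the claiming layer's rows (resp. columns), so the final
#' column clusters partition a subset of the columns.
#'
#' @param X A [signal_matrix()] or numeric matrix.
#' @param max_layers Maximum number of layers to extract.
#' @param seed RNG seed (each layer gets a derived subsampling seed).
#' @param ... Passed on to [ssvd_layer()].
#' @return A `bicluster_solution` with `engine = "ssvd"`.
#' @export
run_ssvd <- function(X, max_layers = 6L, seed = 1L, ...) {
  stopifnot(max_layers >= 1)
  Xw <- unclass(as.matrix(X))
  layers <- list()
  for (l in seq_len(max_layers)) {
    bc <- ssvd_layer(Xw, seed = substream_seed(seed, paste0("layer", l)), ...)
    if (is.null(bc)) break
    layers[[l]] <- bc
    sub <- Xw[bc$rows, bc$cols, drop = FALSE]
    sv <- svd(sub, nu = 1L, nv = 1L)
    Xw[bc$rows, bc$cols] <- sub - sv$d[1L] * tcrossprod(sv$u[, 1L], sv$v[, 1L])
  }
  X0 <- unclass(as.matrix(X))
  layers <- resolve_overlaps(layers, X0)
  new_bicluster_solution(layers, nrow(X0), ncol(X0), "ssvd", seed,
                         rownames(X0), colnames(X0))
}

# enforce disjoint column and row sets across layers: each contested index
# goes to the layer where its mean signal (over that layer's other dimension)
# is largest; earlier layer wins ties
resolve_overlaps <- function(layers, X) {
  if (length(layers) < 2L) return(layers)
  col_owner <- rep(NA_integer_, ncol(X))
  col_strength <- rep(-Inf, ncol(X))
  row_owner <- rep(NA_integer_, nrow(X))
  row_strength <- rep(-Inf, nrow(X))
  for (i in seq_along(layers)) {
    b <- layers[[i]]
    cs <- colMeans(X[b$rows, b$cols, drop = FALSE])
    for (k in seq_along(b$cols)) {
      j <- b$cols[k]
      if (cs[k] > col_strength[j]) {
        col_strength[j] <- cs[k]
        col_owner[j] <- i
      }
    }
    rs <- rowMeans(X[b$rows, b$cols, drop = FALSE])
    for (k in seq_along(b$rows)) {
      j <- b$rows[k]
      if (rs[k] > row_strength[j]) {
        row_strength[j] <- rs[k]
        row_owner[j] <- i
      }
    }
  }
  out <- lapply(seq_along(layers), function(i) {
    b <- layers[[i]]
    b$cols <- b$cols[col_owner[b$cols] == i]
    b$rows <- b$rows[row_owner[b$rows] == i]
    b
  })
  out[vapply(out, function(b) length(b$rows) > 0 && length(b$cols) > 0, logical(1))]
}
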