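#' Combinatorial regression feature selection
#'
#' Expression (CAGE tag counts per promoter) is regressed on the normalized
#' occupancy matrix by OLS; all size-4 experiment subsets are scanned and the
#' "good sets" -- those whose fitted-vs-observed Pearson correlation exceeds
#' a fraction of the full model's -- are tested for over-representation of
#' each experiment by an upper-tail hypergeometric test.
#'
#' @name regression-select
NULL

transform_expression <- function(expression, log_transform) {
  if (log_transform) log1p(expression) else expression
}

#' Full-model correlation of expression with all tracks
#'
#' OLS of (optionally log1p-transformed) expression on all matrix rows plus
#' an intercept; returns the Pearson correlation between fitted and observed
#' values. Collinear predictors are dropped (R's pivoting least squares) with
#' a warning.
#'
#' @param X A [signal_matrix()] or numeric matrix (experiments x promoters).
#' @param expression Numeric vector over promoters.
#' @param log_transform Apply `log1p` to expression before the fit (default
#'   TRUE; CAGE counts are heavily right-skewed).
#' @return The correlation `r_full` (a single number in \[0, 1\]).
#' @export
fit_full <- function(X, expression, log_transform = TRUE) {
  X <- unclass(as.matrix(X))
  if (ncol(X) <= nrow(X) + 1L) {
    abort("need more promoters than experiments + 1")
  }
  y <- transform_expression(as.numeric(expression), log_transform)
  if (stats::sd(y) == 0) abort("expression is constant; correlation undefined")
  d <- as.data.frame(t(X))
  names(d) <- paste0("x", seq_len(nrow(X)))
  fit <- stats::lm(y ~ ., data = d)
  if (anyNA(stats::coef(fit))) warn("collinear predictors dropped from the full model")
  stats::cor(stats::fitted(fit), y)
}

#' Scan all size-4 experiment subsets
#'
#' Enumerates every combination of `subset_size` matrix rows, fits OLS of the
#' (transformed) expression on each subset plus intercept, and records the
#' Pearson correlation of fitted vs observed values. The fits use precomputed
#' covariance sufficient statistics (each subset reduces to a small linear
#' solve), which is what makes the full C(60, 4) = 487,635 scan tractable;
#' the algebra is identical to per-subset `lm()` and is tested against it.
#'
#' @inheritParams fit_full
#' @param subset_size Subset size (default 4).
#' @return A `quadruple_scan` object: tibble `subsets` (list-column `subset`,
#'   column `r`), plus `r_full`, `n_rows`, `subset_size`.
#' @export
scan_quadruples <- function(X, expression, subset_size = 4L,
                            log_transform = TRUE) {
  X <- unclass(as.matrix(X))
  m <- nrow(X)
  if (m < subset_size) abort("need at least `subset_size` experiments")
  y <- transform_expression(as.numeric(expression), log_transform)
  r_full <- fit_full(X, expression, log_transform)
  Xc <- X - rowMeans(X)
  yc <- y - mean(y)
  G <- tcrossprod(Xc)            # m x m centered Gram matrix
  g <- as.numeric(Xc %*% yc)     # covariances with expression
  syy <- sum(yc^2)
  combos <- utils::combn(m, subset_size)
  r <- vapply(seq_len(ncol(combos)), function(i) {
    s <- combos[, i]
    Gs <- G[s, s]
    gs <- g[s]
    beta <- tryCatch(solve(Gs, gs), error = function(e) {
      # rank-deficient subset (e.g. zero-variance rows): pseudo-inverse
      sv <- svd(Gs)
      pos <- sv$d > max(sv$d[1], 0) * 1e-10
      if (!any(pos)) return(rep(0, length(gs)))
      sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], gs)) / sv$d[pos])
    })
    r2 <- sum(beta * gs) / syy
    sqrt(max(min(r2, 1), 0))
  }, numeric(1))
  structure(list(
    subsets = tibble(subset = lapply(seq_len(ncol(combos)),
                                     function(i) combos[, i]),
                     r = r),
    r_full = r_full, n_rows = m, subset_size = as.integer(subset_size),
    row_ids = rownames(X) %||% as.character(seq_len(m))
  ), class = "quadruple_scan")
}

#' @export
print.quadruple_scan <- function(x, ...) {
  cat(sprintf("<quadruple_scan> %d subsets of size %d over %d rows; r_full = %.4f\n",
              nrow(x$subsets), x$subset_size, x$n_rows, x$r_full))
  invisible(x)
}

#' @export
tidy.quadruple_scan <- function(x, ...) {
  mutate(x$subsets,
         subset_id = vapply(.data$subset, paste, character(1), collapse = ","))
}

#' @export
glance.quadruple_scan <- function(x, ...) {
  tibble(n_subsets = nrow(x$subsets), subset_size = x$subset_size,
         n_rows = x$n_rows, r_full = x$r_full, r_max = max(x$subsets$r))
}

#' Select the "good" subsets of a quadruple scan
#'
#' Good sets are the subsets whose correlation is strictly better than
#' `fraction` of the full-model correlation.
#'
#' @param scan A `quadruple_scan`.
#' @param fraction Fraction of `r_full` to beat (default 0.95).
#' @return The rows of `scan$subsets` with `r > fraction * r_full`.
#' @export
good_sets <- function(scan, fraction = 0.95) {
  stopifnot(inherits(scan, "quadruple_scan"))
  filter(scan$subsets, .data$r > fraction * scan$r_full)
}

#' Hypergeometric enrichment of variables among good sets
#'
#' For each experiment (variable) v: the population is all `C(n_rows, s)`
#' subsets, of which `K = C(n_rows - 1, s - 1)` contain v; drawing the
#' `n = |good|` good sets, `k` of them contain v; the upper-tail
#' hypergeometric probability `P(X >= k)` measures over-representation.
#'
#' @param good Tibble of good subsets (from [good_sets()]), with list-column
#'   `subset`.
#' @param n_rows Total number of experiments.
#' @param subset_size Subset size used in the scan (default 4).
#' @param row_ids Optional experiment names.
#' @return A tibble per variable: `variable`, `id`, `k` (good sets containing
#'   it), `K`, `n_good`, `N`, `p` (upper tail), sorted by `p`.
#' @export
enrich_variables <- function(good, n_rows, subset_size = 4L, row_ids = NULL) {
  N <- choose(n_rows, subset_size)
  K <- choose(n_rows - 1, subset_size - 1)
  n_good <- nrow(good)
  k <- integer(n_rows)
  if (n_good > 0) {
    tabulated <- table(factor(unlist(good$subset), levels = seq_len(n_rows)))
    k <- as.integer(tabulated)
  }
  p <- vapply(k, function(ki) {
    if (n_good == 0L) return(1)
    stats::phyper(ki - 1L, K, N - K, n_good, lower.tail = FALSE)
  }, numeric(1))
  tibble(
    variable = seq_len(n_rows),
    id = row_ids %||% as.character(seq_len(n_rows)),
    k = k, K = K, n_good = n_good, N = N, p = p
  ) |>
    arrange(.data$p, .data$variable)
}
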