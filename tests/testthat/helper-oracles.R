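# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct formulas, brute-force enumeration, and
# naive per-cell recomputation.

# closed-form Welch t-test (two-sided), Welch-Satterthwaite df
welch_oracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  vx <- stats::var(x)
  vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p)
}

# all permutations of a vector (rows of the returned matrix)
all_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v))
  out <- NULL
  for (i in seq_along(v)) {
    out <- rbind(out, cbind(v[i], all_perms(v[-i])))
  }
  out
}

# brute-force rectangular LAP maximum: best one-to-one map of rows to columns
lap_oracle <- function(M) {
  ka <- nrow(M)
  kb <- ncol(M)
  n <- max(ka, kb)
  P <- matrix(0, n, n)
  P[seq_len(ka), seq_len(kb)] <- M
  pp <- all_perms(seq_len(n))
  best <- -Inf
  for (r in seq_len(nrow(pp))) {
    s <- sum(P[cbind(seq_len(n), pp[r, ])])
    if (s > best) best <- s
  }
  best
}

# exhaustive upper-tail hypergeometric by enumerating all draws:
# contains = logical over the N population items, n_draw drawn, observed k
hyper_enum_oracle <- function(contains, n_draw, k) {
  N <- length(contains)
  draws <- utils::combn(N, n_draw)
  mean(vapply(seq_len(ncol(draws)), function(i) {
    sum(contains[draws[, i]]) >= k
  }, logical(1)))
}

# brute-force search over all contiguous submatrices for the block
# maximizing sum(block) - 0.5 * area (the planted high-signal block)
block_oracle <- function(X) {
  n <- nrow(X)
  p <- ncol(X)
  best <- list(val = -Inf)
  cs <- apply(apply(X, 2, cumsum), 1, cumsum)  # cs[j, i] = sum X[1:i, 1:j]
  block_sum <- function(i1, i2, j1, j2) {
    s <- cs[j2, i2]
    if (i1 > 1) s <- s - cs[j2, i1 - 1]
    if (j1 > 1) s <- s - cs[j1 - 1, i2]
    if (i1 > 1 && j1 > 1) s <- s + cs[j1 - 1, i1 - 1]
    s
  }
  for (i1 in 1:n) for (i2 in i1:n) for (j1 in 1:p) for (j2 in j1:p) {
    v <- block_sum(i1, i2, j1, j2) - 0.5 * (i2 - i1 + 1) * (j2 - j1 + 1)
    if (v > best$val) best <- list(val = v, rows = i1:i2, cols = j1:j2)
  }
  best
}

# standard 3-block planted fixture used by several suites
planted_3block <- function(n_promoters = 300, n_experiments = 30,
                           noise_sd = 0.2, background_rate = 0.02, seed = 11,
                           block_rows = c(6, 6, 6), block_cols = c(60, 50, 40)) {
  make_planted_matrix(synthetic_config(
    n_promoters, n_experiments,
    blocks = purrr::pmap(list(block_rows, block_cols),
                         function(r, c) list(n_rows = r, n_cols = c, mean_signal = 1)),
    noise_sd = noise_sd, background_rate = background_rate, seed = seed
  ))
}
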