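#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n row_number slice across
#' @importFrom tibble tibble as_tibble
NULL

# Derive a reproducible substream seed from a base seed and a stream name.
# Adding a new generator must not perturb the draws of existing ones, so each
# generator pulls from its own stream instead of sharing one RNG sequence.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_len(nchar(stream)))
  # keep well inside 32-bit integer range
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587L)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Welch two-sample t-test with degenerate-case handling
#'
#' Two-sided Welch (unequal variance) t-test comparing the means of two
#' numeric vectors. Unlike [stats::t.test()], degenerate inputs are mapped to
#' well-defined values so that downstream `-log10(p)` bar heights stay finite:
#' if both groups are constant and equal the result is `t = 0, p = 1`; if both
#' are constant but different, `p = 1e-300` with `t = +/-Inf`.
#'
#' @param x,y Numeric vectors (the two groups).
#' @return A one-row tibble with columns `t`, `p`, and `neglog10p`.
#' @examples
#' welch_test(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_test <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    return(tibble(t = NA_real_, p = NA_real_, neglog10p = NA_real_))
  }
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(tibble(t = 0, p = 1, neglog10p = 0))
    }
    t <- sign(mean(x) - mean(y)) * Inf
    return(tibble(t = t, p = 1e-300, neglog10p = 300))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  p <- max(ht$p.value, 1e-300)
  tibble(t = unname(ht$statistic), p = p, neglog10p = -log10(p))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table by the direct formula. Used to score
#' recovery of planted clusters.
#'
#' @param a,b Vectors of cluster labels (any atomic type), equal length.
#' @return A single number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(NA_real_)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# half-open interval overlap length; intervals are [start, end)
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}
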