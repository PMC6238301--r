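#' Construct a promoter occupancy signal matrix
#'
#' A `signal_matrix` holds normalized ChIP-seq peak heights for a set of
#' promoters: experiments in rows, promoters in columns, all values in
#' \[0, 1\]. It is a plain numeric matrix with dimnames plus per-promoter
#' metadata (TSS coordinate and strand), so base matrix operations work on it
#' directly.
#'
#' @param values Numeric matrix, experiments x promoters, values in \[0, 1\].
#' @param row_ids Character vector of unique experiment names.
#' @param col_ids Character vector of unique promoter ids.
#' @param col_meta Optional tibble of per-promoter metadata (one row per
#'   column of `values`, in order); typically `chrom`, `pos`, `strand`.
#' @return A `signal_matrix` object.
#' @export
signal_matrix <- function(values, row_ids = rownames(values),
                          col_ids = colnames(values), col_meta = NULL) {
  values <- as.matrix(values)
  if (is.null(row_ids)) row_ids <- paste0("exp", seq_len(nrow(values)))
  if (is.null(col_ids)) col_ids <- paste0("prom", seq_len(ncol(values)))
  if (anyDuplicated(row_ids)) abort("experiment ids must be unique")
  if (anyDuplicated(col_ids)) abort("promoter ids must be unique")
  if (length(row_ids) != nrow(values) || length(col_ids) != ncol(values)) {
    abort("id lengths do not match matrix dimensions")
  }
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
    abort("signal_matrix values must be finite and in [0, 1]")
  }
  dimnames(values) <- list(row_ids, col_ids)
  if (!is.null(col_meta)) {
    col_meta <- as_tibble(col_meta)
    if (nrow(col_meta) != ncol(values)) {
      abort("col_meta must have one row per promoter")
    }
  }
  structure(values, col_meta = col_meta, class = c("signal_matrix", "matrix", "array"))
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf(
    "<signal_matrix> %d experiments x %d promoters, range [%.3g, %.3g]\n",
    nrow(x), ncol(x), min(x), max(x)
  ))
  invisible(x)
}

#' @export
`[.signal_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (!is.matrix(out)) return(out)
  meta <- attr(x, "col_meta")
  if (!is.null(meta) && !missing(j)) meta <- meta[j, , drop = FALSE]
  signal_matrix(out, rownames(out), colnames(out), meta)
}

#' Tidy a signal matrix into long form
#'
#' @param x A `signal_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `experiment`, `promoter`, `signal`.
#' @export
tidy.signal_matrix <- function(x, ...) {
  tibble(
    experiment = rep(rownames(x), times = ncol(x)),
    promoter = rep(colnames(x), each = nrow(x)),
    signal = as.numeric(x)
  )
}

#' Height of the peak nearest a TSS
#'
#' Finds, among the peaks on the TSS's chromosome whose summit lies within
#' `tss_window` bp of the TSS, the one minimizing the summit-to-TSS distance,
#' and returns its height. Ties are broken by larger height, then smaller
#' summit coordinate. When no peak qualifies the promoter is devoid of signal
#' and 0 is returned.
#'
#' @param tss_pos TSS coordinate (single integer).
#' @param strand TSS strand; ignored (the search window is symmetric).
#' @param peaks Tibble of peak calls with columns `chrom`, `start`, `end`,
#'   `summit`, `height`, already restricted to the TSS's chromosome.
#' @param tss_window Half-width of the search window in bp (default 1000).
#' @return The height of the nearest qualifying peak, or 0.
#' @export
nearest_peak_height <- function(tss_pos, strand = "+", peaks, tss_window = 1000) {
  if (tss_window <= 0) abort("tss_window must be positive")
  if (nrow(peaks) == 0L) return(0)
  d <- abs(peaks$summit - tss_pos)
  ok <- which(d <= tss_window)
  if (length(ok) == 0L) return(0)
  cand <- ok[order(d[ok], -peaks$height[ok], peaks$summit[ok])]
  peaks$height[cand[1L]]
}

#' Winsorized linear normalization of peak heights
#'
#' Maps nonnegative peak heights within one ChIP-seq experiment to \[0, 1\]:
#' the `k = floor(winsor_fraction * n)` largest values are held out, the
#' remaining values are mapped linearly so the minimum goes to 0 and the
#' largest remaining value to 1, and the held-out values are then set to 1.
#' Degenerate constant input maps to all 0 when the constant is 0 (no signal)
#' and to all 1 otherwise (saturated signal).
#'
#' @param heights Numeric vector of nonnegative peak heights.
#' @param winsor_fraction Fraction of top values to hold out (default 0.0005,
#'   i.e. the top 0.05 percent).
#' @return Numeric vector in \[0, 1\], same length and order as `heights`.
#' @export
normalize_experiment <- function(heights, winsor_fraction = 0.0005) {
  if (length(heights) == 0L) abort("cannot normalize an empty height vector")
  if (winsor_fraction < 0 || winsor_fraction >= 1) {
    abort("winsor_fraction must be in [0, 1)")
  }
  if (any(heights < 0)) abort("peak heights must be nonnegative")
  n <- length(heights)
  k <- floor(winsor_fraction * n)
  out <- numeric(n)
  if (k > 0) {
    ord <- order(heights, decreasing = TRUE)
    held <- ord[seq_len(k)]
    keep <- setdiff(seq_len(n), held)
  } else {
    held <- integer(0)
    keep <- seq_len(n)
  }
  lo <- min(heights[keep])
  hi <- max(heights[keep])
  if (hi == lo) {
    out[keep] <- if (hi == 0) 0 else 1
  } else {
    out[keep] <- (heights[keep] - lo) / (hi - lo)
  }
  out[held] <- 1
  out
}

#' Build the promoters x experiments occupancy matrix
#'
#' For every (experiment, promoter) pair, records the height of the peak
#' closest to the TSS within a symmetric window, then normalizes each
#' experiment's heights to \[0, 1\] with top-fraction winsorization
#' (see [normalize_experiment()]).
#'
#' @param tss Tibble of promoters with columns `id`, `chrom`, `pos`, `strand`
#'   (ids unique).
#' @param peak_sets Named list of peak tibbles, one per experiment, each with
#'   columns `chrom`, `start`, `end`, `summit`, `height`.
#' @param tss_window Half-width of the peak search window in bp.
#' @param winsor_fraction Top fraction winsorized per experiment.
#' @return A [signal_matrix()] with experiments in rows and promoters in
#'   columns.
#' @examples
#' tss <- tibble::tibble(id = c("p1", "p2"), chrom = "chr1",
#'                       pos = c(5000, 50000), strand = "+")
#' pk <- tibble::tibble(chrom = "chr1", start = 4800, end = 5200,
#'                      summit = 5010, height = 12)
#' build_matrix(tss, list(expA = pk))
#' @export
build_matrix <- function(tss, peak_sets, tss_window = 1000,
                         winsor_fraction = 0.0005) {
  tss <- as_tibble(tss)
  if (anyDuplicated(tss$id)) abort("duplicate promoter ids")
  if (is.null(names(peak_sets)) || anyDuplicated(names(peak_sets))) {
    abort("peak_sets must be a uniquely named list of experiments")
  }
  raw <- vapply(peak_sets, function(peaks) {
    peaks <- as_tibble(peaks)
    by_chrom <- split(peaks, peaks$chrom)
    vapply(seq_len(nrow(tss)), function(j) {
      pk <- by_chrom[[tss$chrom[j]]]
      if (is.null(pk)) return(0)
      nearest_peak_height(tss$pos[j], tss$strand[j], pk, tss_window)
    }, numeric(1))
  }, numeric(nrow(tss)))
  if (!is.matrix(raw)) raw <- matrix(raw, nrow = nrow(tss))
  # vapply gives promoters x experiments; transpose to experiments x promoters
  raw <- t(raw)
  norm <- t(apply(raw, 1, normalize_experiment, winsor_fraction = winsor_fraction))
  if (nrow(tss) == 1L) norm <- matrix(norm, nrow = length(peak_sets))
  signal_matrix(
    norm,
    row_ids = names(peak_sets),
    col_ids = tss$id,
    col_meta = tss[, setdiff(names(tss), "id"), drop = FALSE]
  )
}
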