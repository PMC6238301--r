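#' Loops anchored at a promoter region
#'
#' Returns the loops with at least 1 bp overlap (half-open intervals) between
#' one anchor and the promoter region, together with the remote (other)
#' anchor. When both anchors overlap the promoter, the anchor with the larger
#' overlap is taken as the promoter side.
#'
#' @param promoter_region List or one-row tibble with `chrom`, `start`,
#'   `end`.
#' @param loops Tibble with columns `id`, `chromA`, `startA`, `endA`,
#'   `chromB`, `startB`, `endB`.
#' @return The matching rows of `loops` plus `remote_chrom`, `remote_start`,
#'   `remote_end`.
#' @export
promoter_loops <- function(promoter_region, loops) {
  loops <- as_tibble(loops)
  p <- as.list(promoter_region)
  ovA <- ifelse(loops$chromA == p$chrom,
                overlap_len(loops$startA, loops$endA, p$start, p$end), 0)
  ovB <- ifelse(loops$chromB == p$chrom,
                overlap_len(loops$startB, loops$endB, p$start, p$end), 0)
  hit <- ovA > 0 | ovB > 0
  out <- loops[hit, ]
  a_side <- ovA[hit] >= ovB[hit]
  out$remote_chrom <- ifelse(a_side, out$chromB, out$chromA)
  out$remote_start <- ifelse(a_side, out$startB, out$startA)
  out$remote_end <- ifelse(a_side, out$endB, out$endA)
  out
}

# mean of a coverage track over an interval (length-weighted over overlapping
# track segments; uncovered positions count as 0)
coverage_mean <- function(track, chrom, start, end) {
  seg <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(seg) == 0L || end <= start) return(0)
  ov <- overlap_len(seg$start, seg$end, start, end)
  sum(ov * seg$value) / (end - start)
}

#' Select the loop with the strongest remote H3K27ac signal
#'
#' Among a promoter's loops, picks the one maximizing the mean H3K27ac
#' coverage over its remote anchor; ties go to the leftmost remote start.
#'
#' @param loops Output of [promoter_loops()] (needs `remote_*` columns).
#' @param h3k27ac Coverage tibble `chrom`, `start`, `end`, `value`.
#' @return The selected loop row, with `remote_h3k27ac` added.
#' @export
select_loop <- function(loops, h3k27ac) {
  loops <- as_tibble(loops)
  if (nrow(loops) == 0L) abort("no loops to select from")
  sig <- vapply(seq_len(nrow(loops)), function(i) {
    coverage_mean(h3k27ac, loops$remote_chrom[i], loops$remote_start[i],
                  loops$remote_end[i])
  }, numeric(1))
  loops$remote_h3k27ac <- sig
  best <- order(-sig, loops$remote_start)[1L]
  loops[best, ]
}

#' Enhancer class of a remote region
#'
#' Pads the remote interval by `pad` bp on each side and intersects it with
#' the enhancer segmentation: any overlap with a strong segment wins over
#' weak, which wins over none.
#'
#' @param remote List or one-row tibble with `chrom`, `start`, `end`.
#' @param enhancers Tibble `chrom`, `start`, `end`, `state` with state in
#'   strong/weak.
#' @param pad Padding in bp (default 500).
#' @return `"strong"`, `"weak"`, or `"none"`.
#' @export
enhancer_class <- function(remote, enhancers, pad = 500) {
  if (pad < 0) abort("pad must be non-negative")
  r <- as.list(remote)
  s <- r$start - pad
  e <- r$end + pad
  seg <- enhancers[enhancers$chrom == r$chrom &
                     overlap_len(enhancers$start, enhancers$end, s, e) > 0, ]
  if (any(seg$state == "strong")) return("strong")
  if (any(seg$state == "weak")) return("weak")
  "none"
}

#' Re-center a remote region on its CTCF coverage maximum
#'
#' The position with the highest CTCF coverage within the remote interval
#' becomes the new center (ties: leftmost), and the window
#' `[center - flank, center + flank)` is returned. With no coverage at all
#' the geometric midpoint is used and flagged.
#'
#' @param remote List or one-row tibble with `chrom`, `start`, `end`.
#' @param ctcf Coverage tibble `chrom`, `start`, `end`, `value` (segments may
#'   overlap; per-position coverage is their sum).
#' @param flank Half-width of the re-centered window (default 1000).
#' @return A list `chrom`, `start`, `end`, `center`, `flagged` (TRUE when the
#'   midpoint fallback was used).
#' @export
center_remote <- function(remote, ctcf, flank = 1000) {
  r <- as.list(remote)
  seg <- ctcf[ctcf$chrom == r$chrom &
                overlap_len(ctcf$start, ctcf$end, r$start, r$end) > 0, ]
  flagged <- FALSE
  if (nrow(seg) == 0L || all(seg$value <= 0)) {
    center <- floor((r$start + r$end) / 2)
    flagged <- TRUE
  } else {
    # evaluate summed coverage at segment breakpoints inside the remote
    breaks <- sort(unique(pmax(pmin(c(seg$start, seg$end), r$end - 1), r$start)))
    cov <- vapply(breaks, function(x) {
      sum(seg$value[seg$start <= x & seg$end > x])
    }, numeric(1))
    center <- breaks[which.max(cov)]
  }
  list(chrom = r$chrom, start = center - flank, end = center + flank,
       center = center, flagged = flagged)
}

#' Per-promoter loop report and aggregate proportions
#'
#' Runs the full loop pipeline for each promoter: find its loops, select the
#' max-H3K27ac loop, classify the remote anchor against the enhancer
#' segmentation (strong > weak > none), and re-center the remote region on
#' the CTCF coverage maximum.
#'
#' @param promoters Tibble `id`, `chrom`, `start`, `end`.
#' @param loops,enhancers,h3k27ac,ctcf See [promoter_loops()],
#'   [enhancer_class()], [select_loop()], [center_remote()].
#' @param pad Enhancer-overlap padding (default 500).
#' @param flank Re-centering half-width (default 1000).
#' @return A list with `report` (per-promoter tibble: `id`, `n_loops`,
#'   `loop_id`, remote interval, `enhancer_class`, `center`) and
#'   `proportions` (tibble over promoters with >= 1 loop: fraction looping,
#'   and strong/weak/none fractions among those).
#' @export
loop_report <- function(promoters, loops, enhancers, h3k27ac, ctcf,
                        pad = 500, flank = 1000) {
  promoters <- as_tibble(promoters)
  report <- purrr::map_dfr(seq_len(nrow(promoters)), function(i) {
    pl <- promoter_loops(promoters[i, ], loops)
    if (nrow(pl) == 0L) {
      return(tibble(id = promoters$id[i], n_loops = 0L, loop_id = NA_character_,
                    remote_chrom = NA_character_, remote_start = NA_integer_,
                    remote_end = NA_integer_, enhancer_class = NA_character_,
                    center = NA_integer_))
    }
    sel <- select_loop(pl, h3k27ac)
    remote <- list(chrom = sel$remote_chrom, start = sel$remote_start,
                   end = sel$remote_end)
    cls <- enhancer_class(remote, enhancers, pad)
    cen <- center_remote(remote, ctcf, flank)
    tibble(id = promoters$id[i], n_loops = nrow(pl), loop_id = sel$id,
           remote_chrom = sel$remote_chrom, remote_start = sel$remote_start,
           remote_end = sel$remote_end, enhancer_class = cls,
           center = cen$center)
  })
  looped <- filter(report, .data$n_loops > 0)
  proportions <- tibble(
    n_promoters = nrow(report),
    frac_looping = nrow(looped) / nrow(report),
    frac_strong = mean(looped$enhancer_class == "strong"),
    frac_weak = mean(looped$enhancer_class == "weak"),
    frac_none = mean(looped$enhancer_class == "none")
  )
  list(report = report, proportions = proportions)
}
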