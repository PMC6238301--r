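#' Read and write the plain-text interchange formats
#'
#' Lightweight readers/writers for the fixture formats the pipeline
#' consumes: BED6 TSS/enhancer files, 5-column peak files (a documented
#' dialect of MACS subpeak output: chrom, start, end, summit offset within
#' the peak, height), BEDPE-like loop files, bedGraph-like coverage, TSV
#' expression tables, and JSON solutions. All are tab-separated without
#' headers except the matrix/expression TSVs, which carry headers.
#'
#' @name io
NULL

#' @rdname io
#' @param path File path.
#' @return `read_peaks()`: tibble `chrom`, `start`, `end`, `summit`
#'   (absolute), `height`.
#' @export
read_peaks <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                      "summit_offset", "height"),
                  col_types = "ciiid", progress = FALSE) |>
    mutate(summit = .data$start + .data$summit_offset) |>
    select("chrom", "start", "end", "summit", "height")
}

#' @rdname io
#' @param peaks Peak tibble with `chrom`, `start`, `end`, `summit`, `height`.
#' @export
write_peaks <- function(peaks, path) {
  peaks |>
    mutate(summit_offset = .data$summit - .data$start) |>
    select("chrom", "start", "end", "summit_offset", "height") |>
    readr::write_tsv(path, col_names = FALSE)
  invisible(path)
}

#' @rdname io
#' @return `read_tss_bed()`: tibble `chrom`, `pos`, `strand`, `gene_id` (BED6
#'   with the TSS at `start`, gene id in the name field).
#' @export
read_tss_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                      "score", "strand"),
                  col_types = "ciicdc", progress = FALSE) |>
    mutate(pos = .data$start, gene_id = .data$name) |>
    select("chrom", "pos", "strand", "gene_id")
}

#' @rdname io
#' @param tss Tibble `chrom`, `pos`, `strand`, `gene_id`.
#' @export
write_tss_bed <- function(tss, path) {
  tibble(chrom = tss$chrom, start = tss$pos, end = tss$pos + 1L,
         name = tss$gene_id, score = 0, strand = tss$strand) |>
    readr::write_tsv(path, col_names = FALSE)
  invisible(path)
}

#' @rdname io
#' @return `read_bed_states()`: tibble `chrom`, `start`, `end`, `state`
#'   (BED with the segmentation state in the name field).
#' @export
read_bed_states <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "state"),
                  col_types = "ciic", progress = FALSE)
}

#' @rdname io
#' @return `read_loops_bedpe()`: tibble `id`, `chromA`, `startA`, `endA`,
#'   `chromB`, `startB`, `endB`.
#' @export
read_loops_bedpe <- function(path) {
  readr::read_tsv(path, col_names = c("chromA", "startA", "endA",
                                      "chromB", "startB", "endB", "id"),
                  col_types = "ciiciic", progress = FALSE) |>
    select("id", "chromA", "startA", "endA", "chromB", "startB", "endB")
}

#' @rdname io
#' @param loops Loop tibble (see [read_loops_bedpe()]).
#' @export
write_loops_bedpe <- function(loops, path) {
  loops |>
    select("chromA", "startA", "endA", "chromB", "startB", "endB", "id") |>
    readr::write_tsv(path, col_names = FALSE)
  invisible(path)
}

#' @rdname io
#' @return `read_bedgraph()`: tibble `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                  col_types = "ciid", progress = FALSE)
}

#' @rdname io
#' @param x A [signal_matrix()] (for `write_matrix_tsv()`).
#' @export
write_matrix_tsv <- function(x, path) {
  df <- as.data.frame(unclass(as.matrix(x)))
  df <- cbind(experiment = rownames(x), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}

#' @rdname io
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  signal_matrix(m)
}

#' @rdname io
#' @param sol A `bicluster_solution` (for `write_solution_json()`).
#' @export
write_solution_json <- function(sol, path) {
  jsonlite::write_json(list(
    engine = sol$engine, seed = sol$seed,
    biclusters = lapply(sol$biclusters, function(b) {
      list(rows = sol$row_ids[b$rows], cols = sol$col_ids[b$cols],
           score = b$score)
    }),
    unassigned_rows = sol$row_ids[sol$unassigned_rows],
    unassigned_cols = sol$col_ids[sol$unassigned_cols]
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
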