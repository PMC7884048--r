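# Readers and writers for the package's table dialects. All files are UTF-8
# with mandatory headers and '.' decimals; weeks are integers, times in weeks.

#' Write / read an expression matrix as TSV
#'
#' First column `gene_id`, remaining columns one per sample (header row of
#' sample ids), linear-scale intensities.
#'
#' @param expr Genes x samples matrix with gene_id rownames.
#' @param path File path.
#' @return `read_expression_tsv()` returns the matrix; the writer returns
#'   `path` invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  d <- as_tibble(expr, rownames = "gene_id")
  readr::write_tsv(d, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(d)[1] != "gene_id") {
    abort(sprintf("%s: first column must be `gene_id`, found `%s`.",
                  path, names(d)[1]))
  }
  if (anyDuplicated(d$gene_id)) abort(sprintf("%s: duplicate gene_id.", path))
  m <- as.matrix(d[, -1])
  if (!is.numeric(m)) abort(sprintf("%s: non-numeric expression cells.", path))
  rownames(m) <- d$gene_id
  m
}

#' Write / read a design table as CSV (`sample_id,group,sex`)
#'
#' @param design Design tibble.
#' @param path File path.
#' @export
write_design_csv <- function(design, path) {
  assert_design(design)
  readr::write_csv(design, path)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  assert_design(d)
  d
}

#' Write / read a survival table as CSV
#'
#' Columns `animal_id,group,sex,time_weeks,event` with `event` in {0, 1};
#' malformed rows are reported by row number.
#'
#' @param table Survival tibble.
#' @param path File path.
#' @export
write_survival_csv <- function(table, path) {
  assert_survival_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("animal_id", "group", "time_weeks", "event")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s) %s.", path, paste(miss, collapse = ", ")))
  }
  bad <- which(!d$event %in% c(0, 1))
  if (length(bad)) {
    abort(sprintf("%s: `event` must be 0 or 1 (row %d has %s).",
                  path, bad[1], format(d$event[bad[1]])))
  }
  assert_survival_table(d)
  d
}

#' Write / read a long weight table as CSV (`animal_id,group,week,weight_g`)
#'
#' @param weights Weight tibble.
#' @param path File path.
#' @export
write_weights_csv <- function(weights, path) {
  stopifnot(all(c("animal_id", "group", "week", "weight_g") %in% names(weights)))
  readr::write_csv(weights, path)
  invisible(path)
}

#' @rdname write_weights_csv
#' @export
read_weights_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("animal_id", "group", "week", "weight_g")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s) %s.", path, paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(d[, c("animal_id", "week")])) {
    abort(sprintf("%s: more than one weight for an animal-week.", path))
  }
  if (any(d$weight_g <= 0)) abort(sprintf("%s: weights must be > 0 g.", path))
  d
}

#' Read gene lengths from a two-column TSV
#'
#' Columns `gene_id`, `length_bp`.
#'
#' @param path File path.
#' @return Gene-catalog tibble.
#' @export
read_gene_lengths <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(d))) {
    abort(sprintf("%s: need columns `gene_id` and `length_bp`.", path))
  }
  assert_catalog(d)
  as_tibble(d[, c("gene_id", "length_bp")])
}

#' Gene genomic-span lengths from a GTF file
#'
#' Length is the genomic span of each gene: `max(end) - min(start) + 1` over
#' all of the gene's records, 1-based inclusive as in GTF. Genomic spans (not
#' transcript lengths) match the exposure of a transcription unit to
#' transcription-blocking lesions; substitute transcript lengths via
#' [read_gene_lengths()] if preferred.
#'
#' @param path GTF file path.
#' @return Gene-catalog tibble (`gene_id`, `length_bp`).
#' @export
gene_lengths_from_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GTF requires the rtracklayer package.")
  }
  gr <- as.data.frame(rtracklayer::import(path, format = "gtf"))
  if (!"gene_id" %in% names(gr)) {
    abort(sprintf("%s: records carry no gene_id attribute.", path))
  }
  as_tibble(gr[, c("gene_id", "start", "end")]) |>
    group_by(.data$gene_id) |>
    summarise(length_bp = max(.data$end) - min(.data$start) + 1L,
              .groups = "drop")
}
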