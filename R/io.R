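# Readers and writers for the plain-text formats the pipeline consumes.
# Coordinates are 0-based half-open throughout (bedGraph/BED convention).

#' Read a bedGraph coverage track
#'
#' @param path File path (4 columns: chrom, start, end, value; no header;
#'   `track`/`#` lines are skipped).
#' @param value_col Name for the value column (default `"depth"`).
#' @return A tibble `chrom`, `start`, `end`, `<value_col>`.
#' @export
read_bedgraph <- function(path, value_col = "depth") {
  df <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", value_col),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), .default = readr::col_double()
    ),
    comment = "#", progress = FALSE
  )
  df[!startsWith(df$chrom, "track"), ]
}

#' Write a track or profile as bedGraph
#'
#' @param track Tibble with `chrom`, `start`, `end` and the value column.
#' @param path Output path.
#' @param value_col Column written as the bedGraph value.
#' @export
write_bedgraph <- function(track, path, value_col = "depth") {
  check_columns(track, c("chrom", "start", "end", value_col), "track")
  readr::write_tsv(track[, c("chrom", "start", "end", value_col)],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED file (3-6 columns)
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  first <- readr::read_tsv(path, col_names = FALSE, n_max = 1,
                           show_col_types = FALSE, progress = FALSE)
  ncol <- ncol(first)
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(ncol, 6L))]
  readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                  comment = "#", progress = FALSE)
}

#' Write features as BED6
#'
#' @param features Tibble with `chrom`, `start`, `end`; `name`, `score`,
#'   `strand` are filled with defaults when absent.
#' @param path Output path.
#' @export
write_bed <- function(features, path) {
  check_columns(features, c("chrom", "start", "end"), "features")
  f <- features
  if (!"name" %in% names(f)) f$name <- "."
  if (!"score" %in% names(f)) f$score <- 0L
  if (!"strand" %in% names(f)) f$strand <- "."
  readr::write_tsv(f[, c("chrom", "start", "end", "name", "score", "strand")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a mutation table
#'
#' Expects a TSV with header columns `population_id` (or `population`),
#' `gene_id` (or `gene`), `position`, `ref`, `alt`, `effect`,
#' `mutant_read_fraction`.
#'
#' @param path File path.
#' @return Mutation-record tibble.
#' @export
read_mutation_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nm <- names(df)
  nm[nm == "population"] <- "population_id"
  nm[nm == "gene"] <- "gene_id"
  names(df) <- nm
  check_columns(df, c("population_id", "gene_id"), "mutation table")
  df
}

#' Read a gene-model table
#'
#' TSV with header columns `gene_id`, `coding_length` and optionally
#' `regulatory_pad` (default 1,000 when absent); `effective_length` is
#' (re)computed.
#'
#' @param path File path.
#' @return Gene-model tibble.
#' @export
read_gene_models <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("gene_id", "coding_length"), "gene models")
  if (!"regulatory_pad" %in% names(df)) df$regulatory_pad <- 1000
  df$effective_length <- df$coding_length + df$regulatory_pad
  df
}
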