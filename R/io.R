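# Expression-table readers and writers.

EXPRESSION_COLUMNS <- c("experiment", "gene", "time_h", "replicate", "value")

#' Read a long-format expression table
#'
#' Expects a CSV with header `experiment,gene,time_h,replicate,value` and
#' validates it strictly: numeric non-negative values, known gene names, no
#' duplicate (experiment, gene, time, replicate) cells. Errors name the
#' offending rows.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_expression_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           experiment = readr::col_character(),
                           gene = readr::col_character(),
                           time_h = readr::col_double(),
                           replicate = readr::col_integer(),
                           value = readr::col_double()
                         ))
  if (!identical(names(raw), EXPRESSION_COLUMNS)) {
    abort(sprintf("malformed header: expected %s.",
                  paste(EXPRESSION_COLUMNS, collapse = ",")))
  }
  bad_gene <- which(!raw$gene %in% grn_genes())
  if (length(bad_gene)) {
    abort(sprintf("unknown gene name in row(s) %s.",
                  paste(head(bad_gene, 5), collapse = ", ")))
  }
  bad_value <- which(is.na(raw$value) | raw$value < 0)
  if (length(bad_value)) {
    abort(sprintf("negative or missing value in row(s) %s.",
                  paste(head(bad_value, 5), collapse = ", ")))
  }
  dup <- which(duplicated(raw[, c("experiment", "gene", "time_h", "replicate")]))
  if (length(dup)) {
    abort(sprintf("duplicate (experiment, gene, time, replicate) in row(s) %s.",
                  paste(head(dup, 5), collapse = ", ")))
  }
  raw
}

#' @rdname read_expression_csv
#' @param dataset an expression tibble.
#' @export
write_expression_csv <- function(dataset, path) {
  stopifnot(all(EXPRESSION_COLUMNS %in% names(dataset)))
  readr::write_csv(dataset[, EXPRESSION_COLUMNS], path)
  invisible(path)
}
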