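#' Read report-level or aggregated input files
#'
#' `read_reports()` expects one row per report with columns `report_id`,
#' `drug:<name>` ... and `adr:<name>` ... (0/1 flags).  `read_counts()`
#' expects the aggregated long format: `stratum`, `adr`, `count`,
#' `denominator` plus one 0/1 indicator column per drug.  Both are UTF-8
#' delimited text with a header row; the delimiter defaults to a comma.
#'
#' @param path Input file.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A validated tibble (`read_counts()` returns an `adr_counts`).
#' @export
read_reports <- function(path, delim = ",") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  validate_reports(x)
  x
}

#' @rdname read_reports
#' @export
read_counts <- function(path, delim = ",") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  validate_counts(x)
  class(x) <- c("adr_counts", class(x))
  x
}
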