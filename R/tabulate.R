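#' Build a 2x2 contingency table for one drug--ADR pair
#'
#' Summarises a report-level frame into the classical four counts used by
#' disproportionality statistics: `n_ij` (reports mentioning both the target
#' drug and the ADR), `n_i_dot` (reports mentioning the drug), `n_dot_j`
#' (reports mentioning the ADR) and `n` (all reports).  A report contributes
#' at most once to each cell, however many times a term is repeated inside it.
#'
#' @param reports A report-level data frame as returned by [read_reports()]:
#'   one row per report, a `report_id` column, 0/1 columns named `drug:<name>`
#'   and `adr:<name>`.
#' @param drug,adr Names of the target drug and adverse reaction (without the
#'   `drug:`/`adr:` prefixes).
#' @return A one-row tibble of class `adr_contingency` with columns `drug`,
#'   `adr`, `n_ij`, `n_i_dot`, `n_dot_j`, `n`.
#' @examples
#' rep <- tibble::tibble(
#'   report_id = 1:4,
#'   `drug:D` = c(1, 1, 0, 0), `drug:E` = c(0, 0, 1, 1),
#'   `adr:A` = c(1, 0, 1, 0), `adr:B` = c(0, 1, 0, 1)
#' )
#' build_contingency(rep, "D", "A")
#' @export
build_contingency <- function(reports, drug, adr) {
  validate_reports(reports)
  dcol <- paste0("drug:", drug)
  acol <- paste0("adr:", adr)
  if (!dcol %in% names(reports)) {
    stop("unknown drug label: '", drug, "'", call. = FALSE)
  }
  if (!acol %in% names(reports)) {
    stop("unknown ADR label: '", adr, "'", call. = FALSE)
  }
  d <- reports[[dcol]] > 0
  a <- reports[[acol]] > 0
  out <- tibble::tibble(
    drug = drug, adr = adr,
    n_ij = sum(d & a), n_i_dot = sum(d), n_dot_j = sum(a), n = nrow(reports)
  )
  class(out) <- c("adr_contingency", class(out))
  out
}

#' Construct a contingency table directly from the four counts
#'
#' @param n_ij,n_i_dot,n_dot_j,n The pair count, drug margin, ADR margin and
#'   grand total.
#' @param drug,adr Optional labels carried into downstream signal tables.
#' @return A one-row `adr_contingency` tibble.
#' @export
contingency <- function(n_ij, n_i_dot, n_dot_j, n, drug = "drug", adr = "adr") {
  stopifnot(n_ij >= 0, n_i_dot <= n, n_dot_j <= n)
  if (n_ij > min(n_i_dot, n_dot_j) ||
      n - n_i_dot - n_dot_j + n_ij < 0) {
    stop("inconsistent contingency counts", call. = FALSE)
  }
  out <- tibble::tibble(
    drug = drug, adr = adr,
    n_ij = n_ij, n_i_dot = n_i_dot, n_dot_j = n_dot_j, n = n
  )
  class(out) <- c("adr_contingency", class(out))
  out
}

#' Tabulate report-level data into a long model-ready counts frame
#'
#' Materialises the exposure strata implied by one or two target drugs: two
#' strata (exposed / unexposed) for a single drug, four strata (neither,
#' only-first, only-second, both) for a pair.  Each (stratum, ADR) cell holds
#' the number of reports in the stratum mentioning that ADR and the stratum
#' size as denominator; 0/1 indicator columns named after the drugs encode the
#' covariate pattern of each stratum.  ADRs never reported in any stratum are
#' retained with zero counts -- they remain estimable under the mixed model.
#'
#' @inheritParams build_contingency
#' @param drugs Character vector of one or two drug names.
#' @return A tibble of class `adr_counts` with columns `stratum`, `adr`,
#'   `count`, `denominator` and one 0/1 column per drug.
#' @export
to_counts_frame <- function(reports, drugs) {
  validate_reports(reports)
  stopifnot(length(drugs) >= 1)
  dcols <- paste0("drug:", drugs)
  missing <- setdiff(dcols, names(reports))
  if (length(missing) > 0) {
    stop("unknown drug label: '", sub("^drug:", "", missing[1]), "'",
         call. = FALSE)
  }
  acols <- grep("^adr:", names(reports), value = TRUE)
  expo <- as.matrix(reports[dcols]) > 0
  # stratum key: covariate pattern over the target drugs
  # row order: (0,0), (1,0), (0,1), (1,1) -- neither, only-1, only-2, both
  patterns <- expand.grid(rep(list(c(0L, 1L)), length(drugs)))
  names(patterns) <- drugs
  key <- apply(expo, 1, function(r) paste(as.integer(r), collapse = ""))
  rows <- list()
  for (s in seq_len(nrow(patterns))) {
    pat <- as.integer(patterns[s, ])
    lab <- stratum_label(drugs, pat)
    in_s <- key == paste(pat, collapse = "")
    denom <- sum(in_s)
    if (denom == 0) {
      stop("empty stratum '", lab,
           "': no reports with this exposure pattern; ",
           "drop the drug combination", call. = FALSE)
    }
    counts <- if (denom == 1) {
      as.integer(as.matrix(reports[in_s, acols]) > 0)
    } else {
      colSums(as.matrix(reports[in_s, acols]) > 0)
    }
    row <- tibble::tibble(
      stratum = lab,
      adr = sub("^adr:", "", acols),
      count = as.integer(counts),
      denominator = denom
    )
    for (k in seq_along(drugs)) row[[drugs[k]]] <- pat[k]
    rows[[s]] <- row
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("adr_counts", class(out))
  validate_counts(out, drugs)
  out
}

stratum_label <- function(drugs, pattern) {
  if (length(drugs) == 1) {
    return(if (pattern[1] == 1) "exposed" else "unexposed")
  }
  on <- drugs[pattern == 1]
  if (length(on) == 0) "neither" else paste(on, collapse = "+")
}

validate_reports <- function(reports) {
  if (!"report_id" %in% names(reports)) {
    stop("report-level input needs a 'report_id' column", call. = FALSE)
  }
  acols <- grep("^adr:", names(reports), value = TRUE)
  if (length(acols) == 0) {
    stop("no 'adr:<name>' columns found", call. = FALSE)
  }
  flags <- as.matrix(reports[c(grep("^drug:", names(reports), value = TRUE),
                               acols)])
  if (anyNA(flags) || any(flags != 0 & flags != 1)) {
    stop("drug/ADR flags must be 0 or 1", call. = FALSE)
  }
  if (any(rowSums(reports[acols]) == 0)) {
    stop("every report must carry at least one ADR flag", call. = FALSE)
  }
  invisible(reports)
}

validate_counts <- function(frame, drugs = NULL) {
  needed <- c("stratum", "adr", "count", "denominator")
  miss <- setdiff(needed, names(frame))
  if (length(miss) > 0) {
    stop("counts frame is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(frame$count > frame$denominator | frame$count < 0)
  if (length(bad) > 0) {
    stop("count exceeds denominator (or is negative) in row ", bad[1],
         " (stratum '", frame$stratum[bad[1]], "', ADR '",
         frame$adr[bad[1]], "')", call. = FALSE)
  }
  per <- unique(frame[c("stratum", "denominator")])
  if (anyDuplicated(per$stratum)) {
    stop("denominator must be constant within stratum", call. = FALSE)
  }
  if (anyDuplicated(frame[c("stratum", "adr")])) {
    stop("duplicated (stratum, adr) cell", call. = FALSE)
  }
  if (!is.null(drugs)) {
    miss <- setdiff(drugs, names(frame))
    if (length(miss) > 0) {
      stop("counts frame lacks indicator column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  invisible(frame)
}

#' Extract the per-ADR 2x2 table from a two-stratum counts frame
#'
#' @param frame An `adr_counts` frame with strata `exposed`/`unexposed`.
#' @param adr ADR label.
#' @param drug Label used for the output row.
#' @return A one-row `adr_contingency` tibble.
#' @export
counts_to_contingency <- function(frame, adr, drug = "drug") {
  validate_counts(frame)
  sub <- frame[frame$adr == adr, ]
  if (nrow(sub) == 0) stop("unknown ADR label: '", adr, "'", call. = FALSE)
  e <- sub[grepl("^exposed$", sub$stratum), ]
  u <- sub[grepl("^unexposed$", sub$stratum), ]
  stopifnot(nrow(e) == 1, nrow(u) == 1)
  contingency(
    n_ij = e$count, n_i_dot = e$denominator,
    n_dot_j = e$count + u$count, n = e$denominator + u$denominator,
    drug = drug, adr = adr
  )
}
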