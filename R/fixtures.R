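#' Write small deterministic example inputs
#'
#' Generates three plain-text fixtures under `out_dir`: a 1,000-report
#' report-level frame (5 drugs x 20 ADRs), a single-drug counts frame
#' (J = 20) and a DDI counts frame (J = 20), plus `manifest.json` holding
#' MD5 checksums and a frozen classical PRR value for the pair
#' (`drug_1`, `adr_01`) of the report frame.  The same seed always yields
#' byte-identical files.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  set.seed(as.integer(seed))

  n_rep <- 1000; n_drug <- 5; n_adr <- 20
  drugs <- sprintf("drug_%d", seq_len(n_drug))
  adrs <- sprintf("adr_%02d", seq_len(n_adr))
  dmat <- matrix(stats::rbinom(n_rep * n_drug, 1, 0.15), n_rep)
  amat <- matrix(stats::rbinom(n_rep * n_adr, 1, 0.08), n_rep)
  # enforce the at-least-one-ADR invariant
  none <- rowSums(amat) == 0
  amat[cbind(which(none), sample.int(n_adr, sum(none), replace = TRUE))] <- 1L
  cols <- c(list(seq_len(n_rep)),
            lapply(seq_len(n_drug), function(j) dmat[, j]),
            lapply(seq_len(n_adr), function(j) amat[, j]))
  reports <- tibble::as_tibble(
    stats::setNames(cols, c("report_id", paste0("drug:", drugs),
                            paste0("adr:", adrs)))
  )
  f1 <- file.path(out_dir, "reports.csv")
  readr::write_csv(reports, f1)

  single <- to_counts_frame(reports, "drug_1")
  f2 <- file.path(out_dir, "counts_single.csv")
  readr::write_csv(single, f2)

  ddi <- to_counts_frame(reports, c("drug_1", "drug_2"))
  f3 <- file.path(out_dir, "counts_ddi.csv")
  readr::write_csv(ddi, f3)

  frozen <- prr(build_contingency(reports, "drug_1", "adr_01"))
  manifest <- list(
    seed = as.integer(seed),
    files = lapply(
      stats::setNames(c(f1, f2, f3), basename(c(f1, f2, f3))),
      function(f) unname(tools::md5sum(f))),
    frozen_prr_drug_1_adr_01 = frozen$estimate
  )
  f4 <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA), f4)
  invisible(c(f1, f2, f3, f4))
}
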