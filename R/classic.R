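#' Classical disproportionality measures
#'
#' `prr()`, `ror()` and `rrr()` compute the proportional reporting ratio, the
#' reporting odds ratio and the relative reporting ratio from a 2x2
#' contingency table, with log-scale Wald 95% confidence intervals for PRR and
#' ROR and the usual lower-limit-above-one signal rule.
#'
#' With `a = n_ij`, `b = n_i. - n_ij`, `c = n_.j - n_ij` and
#' `d = n - n_i. - n_.j + n_ij`:
#'
#' * PRR `= (a / n_i.) / (c / (n - n_i.))`, with
#'   `SE(log PRR)^2 = 1/a - 1/n_i. + 1/c - 1/(n - n_i.)`;
#' * ROR `= a d / (b c)`, with `SE(log ROR)^2 = 1/a + 1/b + 1/c + 1/d`;
#' * RRR `= n_ij / E_ij` where `E_ij = n_i. n_.j / n` is the expected count
#'   under independence; no interval is attached.
#'
#' When a cell needed by the interval is zero the estimate is still returned
#' where defined, the interval is `NA` and no signal is declared; this is the
#' structural weakness of the classical measures that the mixed model
#' removes.  An optional Haldane correction (adding 1/2 to every cell) is
#' available behind `haldane = TRUE` and is off by default.
#'
#' @param table An `adr_contingency` row (see [build_contingency()]), possibly
#'   with several rows; all rows are processed.
#' @param alpha Two-sided confidence level complement (default 0.05).
#' @param haldane Add 0.5 to all four cells before computing (default FALSE).
#' @return A tibble of class `adr_signals` with columns `drug`, `adr`,
#'   `measure`, `estimate`, `ci_lower`, `ci_upper`, `signal`, `method`.
#' @examples
#' prr(contingency(20, 1000, 120, 100000))
#' ror(contingency(20, 1000, 120, 100000))
#' @export
prr <- function(table, alpha = 0.05, haldane = FALSE) {
  cells <- contingency_cells(table, haldane)
  with(cells, {
    if (any(n_i_dot <= 0) || any(n - n_i_dot <= 0)) {
      stop("PRR needs n_i. > 0 and n - n_i. > 0", call. = FALSE)
    }
    est <- (a / n_i_dot) / (c / (n - n_i_dot))
    se2 <- 1 / a - 1 / n_i_dot + 1 / c - 1 / (n - n_i_dot)
    ok <- a > 0 & c > 0
    make_signal_rows(table, "PRR", est, se2, ok, alpha, "traditional")
  })
}

#' @rdname prr
#' @export
ror <- function(table, alpha = 0.05, haldane = FALSE) {
  cells <- contingency_cells(table, haldane)
  with(cells, {
    if (any(n_i_dot <= 0) || any(n - n_i_dot <= 0)) {
      stop("ROR needs n_i. > 0 and n - n_i. > 0", call. = FALSE)
    }
    est <- (a * d) / (b * c)
    se2 <- 1 / a + 1 / b + 1 / c + 1 / d
    ok <- a > 0 & b > 0 & c > 0 & d > 0
    make_signal_rows(table, "ROR", est, se2, ok, alpha, "traditional")
  })
}

#' @rdname prr
#' @export
rrr <- function(table) {
  cells <- contingency_cells(table, haldane = FALSE)
  with(cells, {
    if (any(n_i_dot <= 0) || any(n_dot_j <= 0)) {
      stop("RRR needs both margins positive", call. = FALSE)
    }
    est <- a / (n_i_dot * n_dot_j / n)
    out <- tibble::tibble(
      drug = table$drug, adr = table$adr, measure = "RRR",
      estimate = est, ci_lower = NA_real_, ci_upper = NA_real_,
      signal = FALSE, method = "traditional"
    )
    class(out) <- c("adr_signals", class(out))
    out
  })
}

contingency_cells <- function(table, haldane) {
  h <- if (isTRUE(haldane)) 0.5 else 0
  a <- table$n_ij + h
  b <- table$n_i_dot - table$n_ij + h
  c <- table$n_dot_j - table$n_ij + h
  d <- table$n - table$n_i_dot - table$n_dot_j + table$n_ij + h
  if (any(c(a, b, c, d) < 0)) {
    stop("negative derived cell: inconsistent contingency table",
         call. = FALSE)
  }
  list(a = a, b = b, c = c, d = d,
       n_i_dot = table$n_i_dot + 2 * h, n_dot_j = table$n_dot_j + 2 * h,
       n = table$n + 4 * h)
}

make_signal_rows <- function(table, measure, est, se2, ok, alpha, method) {
  z <- stats::qnorm(1 - alpha / 2)
  se <- ifelse(ok, sqrt(pmax(se2, 0)), NA_real_)
  lo <- ifelse(ok, exp(log(est) - z * se), NA_real_)
  hi <- ifelse(ok, exp(log(est) + z * se), NA_real_)
  out <- tibble::tibble(
    drug = table$drug, adr = table$adr, measure = measure,
    estimate = est, ci_lower = lo, ci_upper = hi,
    signal = !is.na(lo) & lo > 1, method = method
  )
  class(out) <- c("adr_signals", class(out))
  out
}

#' Write a signal table to delimited text
#'
#' Columns are emitted in the fixed order `drug, adr, measure, estimate,
#' ci_lower, ci_upper, signal, method`.
#'
#' @param signals An `adr_signals` tibble.
#' @param path Output file; `","` or `"\t"` delimiter via `delim`.
#' @param delim Field delimiter (default comma).
#' @export
write_signals <- function(signals, path, delim = ",") {
  cols <- c("drug", "adr", "measure", "estimate", "ci_lower", "ci_upper",
            "signal", "method")
  readr::write_delim(signals[cols], path, delim = delim, na = "")
  invisible(path)
}
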