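#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted screening mixed model
#'
#' One row per fixed effect (`effect = "fixed"`, with Wald statistics from
#' the prediction covariance) and one per variance component
#' (`effect = "ran_pars"`).
#'
#' @param x An `adr_glmm` fit.
#' @param ... Unused.
#' @export
tidy.adr_glmm <- function(x, ...) {
  se <- sqrt(diag(x$beta_cov))
  fixed <- tibble::tibble(
    effect = "fixed",
    term = names(x$beta),
    estimate = as.numeric(x$beta),
    std.error = se,
    statistic = as.numeric(x$beta) / se,
    p.value = 2 * stats::pnorm(-abs(as.numeric(x$beta) / se))
  )
  ran <- tibble::tibble(
    effect = "ran_pars",
    term = paste0("var_", x$blocks),
    estimate = as.numeric(x$gamma),
    std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
  )
  dplyr::bind_rows(fixed, ran)
}

#' Glance at a fitted screening mixed model
#'
#' @inheritParams tidy.adr_glmm
#' @export
glance.adr_glmm <- function(x, ...) {
  tibble::tibble(
    nobs = x$nobs,
    n_groups = length(x$group_levels),
    family = x$family,
    converged = x$converged,
    n_outer_iter = x$n_outer_iter,
    objective = unname(x$pseudo_trace[nrow(x$pseudo_trace), "objective"]),
    phi = x$phi
  )
}

#' @exportS3Method base::print
print.adr_signals <- function(x, ...) {
  cat("ADR signal table (", sum(x$signal), " of ", nrow(x),
      " rows flagged)\n", sep = "")
  NextMethod()
}
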