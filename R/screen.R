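#' Screening configuration
#'
#' @param measure `"PRR"` (Poisson mixed model, log link, offset
#'   log-denominator) or `"ROR"` (logistic mixed model with trials).
#' @param drugs Character vector of one or two drug names matching indicator
#'   columns of the counts frame.
#' @param alpha Two-sided interval level complement (default 0.05).
#' @param control Engine options, see [glmm_control()].
#' @export
screen_config <- function(measure = c("PRR", "ROR"), drugs,
                          alpha = 0.05, control = glmm_control()) {
  measure <- match.arg(measure)
  stopifnot(length(drugs) %in% c(1L, 2L), alpha > 0, alpha < 1)
  list(measure = measure, drugs = drugs, alpha = alpha, control = control)
}

# order a counts frame by (stratum given pattern order, adr); returns the
# pieces needed to build a model
prepare_frame <- function(frame, drugs, n_strata) {
  validate_counts(frame, drugs)
  strata <- unique(frame[c("stratum", drugs)])
  if (nrow(strata) != n_strata) {
    stop("expected ", n_strata, " exposure strata, found ", nrow(strata),
         call. = FALSE)
  }
  frame$adr <- factor(frame$adr, levels = unique(frame$adr))
  frame <- frame[order(frame$adr, frame$stratum), ]
  J <- nlevels(frame$adr)
  if (J < 2) {
    stop("only one ADR present: a mixed screen needs J >= 2; ",
         "use prr()/ror() on the 2x2 table instead", call. = FALSE)
  }
  list(frame = frame, J = J)
}

mixed_rows <- function(fit, frame, drug_label, fixed_index, block,
                       measure, alpha) {
  J <- length(fit$group_levels)
  K <- length(fit$blocks)
  p <- length(fit$beta)
  lf <- matrix(0, p, J); lf[fixed_index, ] <- 1
  k <- match(block, fit$blocks)
  lr <- matrix(0, K * J, J)
  lr[cbind((k - 1L) * J + seq_len(J), seq_len(J))] <- 1
  pr <- predict_linear_combo(fit, lf, lr)
  z <- stats::qnorm(1 - alpha / 2)
  out <- tibble::tibble(
    drug = drug_label,
    adr = fit$group_levels,
    measure = measure,
    estimate = exp(pr$estimate),
    ci_lower = exp(pr$estimate - z * pr$se),
    ci_upper = exp(pr$estimate + z * pr$se),
    signal = exp(pr$estimate - z * pr$se) > 1,
    method = "mixed"
  )
  class(out) <- c("adr_signals", class(out))
  out
}

#' Screen all ADRs of one drug with the mixed model
#'
#' Fits a single generalized linear mixed model to the two-stratum counts
#' frame: fixed intercept and drug effect, a per-ADR random intercept and a
#' per-ADR random drug slope (one shared variance component each).  The
#' ADR-specific measure is `exp(beta_drug + b_j)` with a prediction interval
#' from the joint coefficient covariance; every ADR receives an interval,
#' including those never reported with the drug.
#'
#' @param frame An `adr_counts` frame with strata `exposed`/`unexposed`
#'   (see [to_counts_frame()] or [generate_single()]).
#' @param config A [screen_config()] with one drug.
#' @return An `adr_signals` tibble with one row per ADR, plus attributes
#'   `fit` (the `adr_glmm` object).
#' @export
screen_single <- function(frame, config) {
  stopifnot(length(config$drugs) == 1)
  drug <- config$drugs
  prep <- prepare_frame(frame, drug, 2L)
  fr <- prep$frame
  x <- fr[[drug]]
  X <- cbind(`(Intercept)` = 1, x = x)
  spec <- make_screen_spec(fr, X, config,
                           random = list(intercept = rep(1, nrow(fr)),
                                         slope = x))
  fit <- fit_glmm(spec, config$control)
  out <- mixed_rows(fit, fr, drug, fixed_index = 2L, block = "slope",
                    measure = config$measure, alpha = config$alpha)
  attr(out, "fit") <- fit
  out
}

#' Screen a drug pair for multiplicative interaction signals
#'
#' Fits one mixed model to the four-stratum counts frame with fixed effects
#' for each drug and their product, and four per-ADR random blocks (intercept,
#' each drug slope, interaction slope).  Three signal rows are produced per
#' ADR: each single drug (`exp(beta_i + b_ij)`) and the interaction
#' (`exp(beta_ii' + b_ii'j)`); a drug--drug-interaction signal is an
#' interaction interval whose lower limit exceeds 1 (a multiplicative-scale
#' criterion).
#'
#' @param frame An `adr_counts` frame with the four exposure strata
#'   (see [to_counts_frame()] with two drugs or [generate_ddi()]).
#' @param config A [screen_config()] with two drugs.
#' @return An `adr_signals` tibble with three rows per ADR.
#' @export
screen_ddi <- function(frame, config) {
  stopifnot(length(config$drugs) == 2)
  d1 <- config$drugs[1]; d2 <- config$drugs[2]
  prep <- prepare_frame(frame, config$drugs, 4L)
  fr <- prep$frame
  if (all(fr$count[fr[[d1]] == 1 & fr[[d2]] == 1] == 0) &&
      all(fr$denominator[fr[[d1]] == 1 & fr[[d2]] == 1] == 0)) {
    stop("empty 'both drugs' stratum", call. = FALSE)
  }
  x1 <- fr[[d1]]; x2 <- fr[[d2]]
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2, x12 = x1 * x2)
  spec <- make_screen_spec(fr, X, config,
                           random = list(intercept = rep(1, nrow(fr)),
                                         slope1 = x1, slope2 = x2,
                                         slope12 = x1 * x2))
  fit <- fit_glmm(spec, config$control)
  out <- dplyr::bind_rows(
    mixed_rows(fit, fr, d1, 2L, "slope1", config$measure, config$alpha),
    mixed_rows(fit, fr, d2, 3L, "slope2", config$measure, config$alpha),
    mixed_rows(fit, fr, paste(d1, d2, sep = ":"), 4L, "slope12",
               config$measure, config$alpha)
  )
  class(out) <- c("adr_signals", class(out))
  attr(out, "fit") <- fit
  out
}

make_screen_spec <- function(fr, X, config, random) {
  if (config$measure == "PRR") {
    glmm_spec(fr$count, X, family = "poisson",
              offset = log(fr$denominator),
              random = random, group = fr$adr)
  } else {
    glmm_spec(fr$count, X, family = "binomial", trials = fr$denominator,
              random = random, group = fr$adr)
  }
}

#' Per-ADR fixed-effect comparator screen
#'
#' The classical approach: a separate fixed-effect GLM per ADR (Poisson with
#' offset for PRR, logistic for ROR) with Wald intervals.  For the two-stratum
#' layout this is exactly [prr()]/[ror()] applied to each ADR's 2x2 table; for
#' the four-stratum layout it is the saturated model with both drugs and their
#' interaction, whose maximum-likelihood contrasts have closed form.  Zero
#' cells leave the interval undefined and the ADR unflagged.
#'
#' @inheritParams screen_single
#' @param config A [screen_config()]; one drug gives one row per ADR, two
#'   drugs give three rows per ADR as in [screen_ddi()].
#' @return An `adr_signals` tibble with `method = "traditional"`.
#' @export
screen_classic <- function(frame, config) {
  if (length(config$drugs) == 1) {
    screen_classic_single(frame, config)
  } else {
    screen_classic_ddi(frame, config)
  }
}

screen_classic_single <- function(frame, config) {
  drug <- config$drugs
  prep <- prepare_frame(frame, drug, 2L)
  fr <- prep$frame
  e <- fr[fr[[drug]] == 1, ]
  u <- fr[fr[[drug]] == 0, ]
  stopifnot(all(e$adr == u$adr))
  tab <- tibble::tibble(
    drug = drug, adr = as.character(e$adr),
    n_ij = e$count, n_i_dot = e$denominator,
    n_dot_j = e$count + u$count, n = e$denominator + u$denominator
  )
  if (config$measure == "PRR") {
    prr(tab, alpha = config$alpha)
  } else {
    ror(tab, alpha = config$alpha)
  }
}

# saturated 4-stratum GLM contrasts in closed form (identical to the IRLS
# solution of the per-ADR model with D1, D2 and D1:D2)
screen_classic_ddi <- function(frame, config) {
  d1 <- config$drugs[1]; d2 <- config$drugs[2]
  prep <- prepare_frame(frame, config$drugs, 4L)
  fr <- prep$frame
  get <- function(a, b) fr[fr[[d1]] == a & fr[[d2]] == b, ]
  s00 <- get(0, 0); s10 <- get(1, 0); s01 <- get(0, 1); s11 <- get(1, 1)
  y <- cbind(s00$count, s10$count, s01$count, s11$count)
  m <- cbind(s00$denominator, s10$denominator, s01$denominator,
             s11$denominator)
  if (config$measure == "PRR") {
    lam <- log(y) - log(m)                 # log rates
    v <- 1 / y                             # Poisson log-count variance
  } else {
    lam <- log(y) - log(m - y)             # log odds
    v <- 1 / y + 1 / (m - y)
  }
  contrast <- function(w) list(est = as.numeric(lam %*% w),
                               se2 = as.numeric(v %*% (w^2)))
  eff1 <- contrast(c(-1, 1, 0, 0))
  eff2 <- contrast(c(-1, 0, 1, 0))
  int <- contrast(c(1, -1, -1, 1))
  rows <- function(drug_label, ct, cells) {
    ok <- apply(cells, 1, function(r) all(is.finite(r)))
    make_signal_rows(
      tibble::tibble(drug = drug_label, adr = as.character(s00$adr)),
      config$measure, exp(ct$est), ct$se2, ok & is.finite(ct$est),
      config$alpha, "traditional")
  }
  fin <- function(...) do.call(cbind, lapply(list(...), function(x) x))
  out <- dplyr::bind_rows(
    rows(d1, eff1, fin(lam[, 1], lam[, 2])),
    rows(d2, eff2, fin(lam[, 1], lam[, 3])),
    rows(paste(d1, d2, sep = ":"), int, lam)
  )
  class(out) <- c("adr_signals", class(out))
  out
}
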