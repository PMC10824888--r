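#' Single-drug simulation scenario
#'
#' Defines the binomial data-generating process for single-drug screening
#' experiments: for each of `J` ADRs, the exposed count is
#' `Bin(n_exposed, p_exposed)` and the unexposed count is
#' `Bin(n_total - n_exposed, p_unexposed)`, drawn independently.
#' Probabilities are given in percent, as usually tabulated
#' (0.05 means 0.05%).
#'
#' @param p_unexposed,p_exposed Incidence probabilities in percent.
#' @param n_total Total number of reports (default 1e7).
#' @param n_exposed Reports with the target drug (default 1e4).
#' @param J Number of ADR types (default 100).
#' @param reps Number of replications (default 1000).
#' @param seed Root seed; per-replicate streams derive from
#'   `(seed, rep_index)`.
#' @return A `scenario_spec` list.
#' @export
scenario_single <- function(p_unexposed, p_exposed,
                            n_total = 1e7, n_exposed = 1e4,
                            J = 100, reps = 1000, seed = 1) {
  check_percent(c(p_unexposed, p_exposed))
  structure(
    list(mode = "single", J = as.integer(J), reps = as.integer(reps),
         seed = as.integer(seed), n_total = n_total, n_exposed = n_exposed,
         p_unexposed = p_unexposed, p_exposed = p_exposed),
    class = "scenario_spec"
  )
}

#' Drug--drug-interaction simulation scenario
#'
#' Four independent binomial draws per ADR over the exposure strata
#' (neither, only drug 1, only drug 2, both), with the conventional stratum
#' sizes 1e7 / 1e5 / 1e5 / 1e4.  The multiplicative interaction null holds
#' when `p00 * p11 / (p10 * p01) = 1`.
#'
#' @param p Length-4 vector of incidence probabilities in percent, ordered
#'   `(p00, p10, p01, p11)`.
#' @param sizes Stratum sizes, same order.
#' @inheritParams scenario_single
#' @export
scenario_ddi <- function(p, sizes = c(1e7, 1e5, 1e5, 1e4),
                         J = 100, reps = 1000, seed = 1) {
  stopifnot(length(p) == 4, length(sizes) == 4, all(sizes > 0))
  check_percent(p)
  structure(
    list(mode = "ddi", J = as.integer(J), reps = as.integer(reps),
         seed = as.integer(seed), sizes = sizes, p = p),
    class = "scenario_spec"
  )
}

# percent-scale probabilities; 0 is allowed as a degenerate (all-zero) limit
check_percent <- function(p) {
  pr <- p / 100
  if (any(pr < 0) || any(pr >= 1)) {
    stop("probabilities must be in [0, 100) percent", call. = FALSE)
  }
  invisible(pr)
}

# deterministic per-replicate substream: same (seed, rep) => same draws,
# distinct reps => distinct streams
rep_seed <- function(seed, rep_index) {
  as.integer((as.double(seed) * 48271 + as.double(rep_index) * 9973) %%
               2147483629)
}

#' Generate one replicate of a single-drug counts frame
#'
#' @param spec A [scenario_single()] specification.
#' @param rep_index Replicate number (>= 1).
#' @return An `adr_counts` frame with strata `exposed`/`unexposed` and drug
#'   indicator column `drug1`.
#' @export
generate_single <- function(spec, rep_index = 1) {
  stopifnot(inherits(spec, "scenario_spec"), spec$mode == "single")
  set.seed(rep_seed(spec$seed, rep_index))
  J <- spec$J
  y1 <- stats::rbinom(J, spec$n_exposed, spec$p_exposed / 100)
  y0 <- stats::rbinom(J, spec$n_total - spec$n_exposed,
                      spec$p_unexposed / 100)
  adr <- sprintf("adr_%03d", seq_len(J))
  out <- tibble::tibble(
    stratum = rep(c("unexposed", "exposed"), each = J),
    adr = c(adr, adr),
    count = c(y0, y1),
    denominator = rep(c(spec$n_total - spec$n_exposed, spec$n_exposed),
                      each = J),
    drug1 = rep(c(0L, 1L), each = J)
  )
  class(out) <- c("adr_counts", class(out))
  out
}

#' Generate one replicate of a DDI counts frame
#'
#' @param spec A [scenario_ddi()] specification.
#' @inheritParams generate_single
#' @return An `adr_counts` frame with four strata and indicator columns
#'   `drug1`, `drug2`.
#' @export
generate_ddi <- function(spec, rep_index = 1) {
  stopifnot(inherits(spec, "scenario_spec"), spec$mode == "ddi")
  set.seed(rep_seed(spec$seed, rep_index))
  J <- spec$J
  pr <- spec$p / 100
  counts <- lapply(1:4, function(s) stats::rbinom(J, spec$sizes[s], pr[s]))
  adr <- sprintf("adr_%03d", seq_len(J))
  lab <- c("neither", "drug1", "drug2", "drug1+drug2")
  x1 <- c(0L, 1L, 0L, 1L); x2 <- c(0L, 0L, 1L, 1L)
  out <- tibble::tibble(
    stratum = rep(lab, each = J),
    adr = rep(adr, 4),
    count = unlist(counts),
    denominator = rep(spec$sizes, each = J),
    drug1 = rep(x1, each = J),
    drug2 = rep(x2, each = J)
  )
  class(out) <- c("adr_counts", class(out))
  out
}

#' Run a flag-rate experiment over simulated replicates
#'
#' For each replicate: generate a counts frame, apply the requested screening
#' methods, and record the proportion of ADRs flagged (the false-positive
#' rate under a null scenario, the sensitivity otherwise; for DDI scenarios
#' the interaction signal is scored).  Replicates where the mixed-model
#' engine fails to converge are counted and excluded, never silently
#' dropped; a warning is attached if more than 5% fail.
#'
#' @param spec A [scenario_single()] or [scenario_ddi()] specification.
#' @param methods Subset of `"mixed-prr"`, `"mixed-ror"`, `"classic-prr"`,
#'   `"classic-ror"`.
#' @param reps Optional override of `spec$reps` (e.g. for smoke runs).
#' @param alpha Signal level (default 0.05).
#' @param control Engine control for the mixed methods.
#' @return A tibble of class `adr_sim`: one row per method with the flag
#'   proportion (percent), its Monte-Carlo standard error (percent, the
#'   standard deviation of per-replicate proportions over the square root of
#'   completed replicates), completed replicate and convergence-failure
#'   counts.  The scenario is attached as attribute `spec`.
#' @export
run_experiment <- function(spec,
                           methods = c("mixed-prr", "classic-prr"),
                           reps = NULL, alpha = 0.05,
                           control = glmm_control()) {
  methods <- match.arg(methods,
                       c("mixed-prr", "mixed-ror", "classic-prr",
                         "classic-ror"),
                       several.ok = TRUE)
  reps <- if (is.null(reps)) spec$reps else as.integer(reps)
  drugs <- if (spec$mode == "single") "drug1" else c("drug1", "drug2")
  rates <- stats::setNames(
    replicate(length(methods), numeric(0), simplify = FALSE), methods)
  failures <- stats::setNames(integer(length(methods)), methods)

  for (r in seq_len(reps)) {
    frame <- if (spec$mode == "single") {
      generate_single(spec, r)
    } else {
      generate_ddi(spec, r)
    }
    for (m in methods) {
      measure <- if (grepl("prr$", m)) "PRR" else "ROR"
      cfg <- screen_config(measure, drugs, alpha = alpha, control = control)
      res <- if (grepl("^classic", m)) {
        screen_classic(frame, cfg)
      } else {
        tryCatch(
          if (spec$mode == "single") screen_single(frame, cfg)
          else screen_ddi(frame, cfg),
          error = function(e) NULL
        )
      }
      if (is.null(res)) {
        failures[m] <- failures[m] + 1L
        next
      }
      if (spec$mode == "ddi") {
        res <- res[res$drug == "drug1:drug2", ]
      }
      rates[[m]] <- c(rates[[m]], mean(res$signal))
    }
  }

  out <- tibble::tibble(
    method = methods,
    measure = ifelse(grepl("prr$", methods), "PRR", "ROR"),
    flag_rate = purrr::map_dbl(methods, ~ mean(rates[[.x]]) * 100),
    mc_se = purrr::map_dbl(
      methods,
      ~ stats::sd(rates[[.x]]) / sqrt(length(rates[[.x]])) * 100),
    reps_completed = purrr::map_int(methods, ~ length(rates[[.x]])),
    convergence_failures = as.integer(failures[methods])
  )
  if (any(failures > 0.05 * reps)) {
    warning("more than 5% of replicates failed to converge for: ",
            paste(names(failures)[failures > 0.05 * reps], collapse = ", "))
  }
  class(out) <- c("adr_sim", class(out))
  attr(out, "spec") <- spec
  out
}

#' Serialize an experiment result to JSON
#'
#' @param result An `adr_sim` tibble.
#' @param path Optional output file.
#' @export
sim_to_json <- function(result, path = NULL) {
  spec <- attr(result, "spec")
  obj <- list(scenario = unclass(spec), results = result)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
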