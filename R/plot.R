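#' Forest-style plot of a signal table
#'
#' Estimates and 95% intervals per ADR on a log scale, flagged ADRs
#' highlighted, the null value 1 marked.
#'
#' @param object An `adr_signals` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adr_signals <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$estimate)
  df$adr <- factor(df$adr, levels = unique(df$adr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$adr,
                                   colour = .data$signal)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
      height = 0, na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$drug), scales = "free_x") +
    ggplot2::labs(x = paste(unique(df$measure), collapse = "/"),
                  y = NULL, colour = "signal") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Bar chart of experiment flag rates
#'
#' @param object An `adr_sim` tibble from [run_experiment()].
#' @param ... Unused.
#' @export
autoplot.adr_sim <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$method, y = .data$flag_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$flag_rate - .data$mc_se,
                   ymax = .data$flag_rate + .data$mc_se),
      width = 0.2) +
    ggplot2::labs(x = NULL, y = "flagged ADRs (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
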