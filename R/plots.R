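#' Plot a cohort trace
#'
#' State occupancy over time: the fraction of the cohort in each health
#' state at each cycle, reproducing the mood-state prevalence view of the
#' modeled epidemiology.
#'
#' @param object A `bd_trace` from [run_cohort_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bd_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = dplyr::all_of(ALL_STATES),
                              names_to = "state", values_to = "occupancy")
  long$state <- factor(long$state, levels = ALL_STATES)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cohort age (years)", y = "Fraction of cohort",
                  colour = "State") +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness plane
#'
#' Scatter of the per-iteration incremental QALYs (x) against incremental
#' costs (y) from a probabilistic sensitivity analysis, with an optional
#' willingness-to-pay line through the origin.
#'
#' @param object A `bd_psa` from [run_psa()].
#' @param wtp Optional willingness-to-pay threshold to draw (euros per QALY).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bd_psa <- function(object, wtp = 50000, ...) {
  p <- ggplot2::ggplot(object$draws,
                       ggplot2::aes(x = .data$delta_qaly,
                                    y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental costs (EUR)") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed")
  }
  p
}

#' Plot a cost-effectiveness acceptability curve
#'
#' Probability of positive net monetary benefit as a function of the
#' willingness-to-pay threshold.
#'
#' @param psa A `bd_psa` (its stored CEAC is used) or a data frame with
#'   columns `wtp` and `probability`.
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa) {
  curve <- if (inherits(psa, "bd_psa")) psa$ceac else psa
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (EUR per QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
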