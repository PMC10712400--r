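#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a projected prevalence trajectory
#'
#' One line per weight state, prevalence against decade.
#'
#' @param object A `markov_projection` from [project()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.markov_projection <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$decade, y = .data$prob,
                               colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Decades from survey", y = "Prevalence",
                  colour = "Weight state") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap confidence bands around projected prevalences
#'
#' Point trajectory with a percentile ribbon per state.
#'
#' @param object A `bootstrap_bands` from [bootstrap_projection()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bootstrap_bands <- function(object, ...) {
  lvl <- 100 * (1 - attr(object, "alpha"))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$decade, y = .data$point,
                               colour = .data$state, fill = .data$state)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Decades from survey", y = "Prevalence",
                  colour = "Weight state", fill = "Weight state",
                  subtitle = paste0(format(lvl), "% percentile bootstrap bands")) +
    ggplot2::theme_minimal()
}

#' Plot the decade weight-change histogram
#'
#' @param derived Derived records from [derive_cohort()].
#' @param bin_width_kg Bin width in kg (default 5).
#' @return A ggplot.
#' @export
plot_change_histogram <- function(derived, bin_width_kg = 5) {
  h <- change_histogram(derived, bin_width_kg)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$midpoint, y = .data$count)) +
    ggplot2::geom_col(width = bin_width_kg, fill = "steelblue",
                      colour = "white") +
    ggplot2::labs(x = "10-year weight change (kg)", y = "Individuals") +
    ggplot2::theme_minimal()
}
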