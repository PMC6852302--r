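# ggplot2 displays mirroring the model's standard figures.

#' Plot methods
#'
#' `autoplot()` draws the standard display for each result type: stacked pool
#' areas for a trajectory, relative-benefit curves against DF (one line per
#' timeframe, 100% parity line) for a comparison, box plots for a Monte Carlo
#' result, and cumulative benefit curves for a scenario.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name cbenefit-plots
NULL

#' @rdname cbenefit-plots
#' @method autoplot cb_pool_trajectory
#' @export
autoplot.cb_pool_trajectory <- function(object, ...) {
  dat <- tidy.cb_pool_trajectory(object)
  dat$pool <- factor(dat$pool, levels = c("bm_above", "bm_below", "dom", "soc"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$year, y = .data$stock,
                                    fill = .data$pool)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Year since start of conversion",
                  y = "Carbon stock (tC/ha)",
                  fill = "Pool",
                  title = sprintf("Carbon pools, %s option",
                                  attr(object, "option") %||% "")) +
    ggplot2::theme_minimal()
}

#' @rdname cbenefit-plots
#' @method autoplot cb_comparison
#' @export
autoplot.cb_comparison <- function(object, ...) {
  dat <- object$table
  dat$tf <- factor(dat$tf)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$df, y = .data$ratio_pct,
                                    colour = .data$tf)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::labs(x = "Displacement factor",
                  y = "Relative C benefit of succession (%)",
                  colour = "Timeframe (yr)") +
    ggplot2::theme_minimal()
}

#' @rdname cbenefit-plots
#' @method autoplot cb_montecarlo
#' @export
autoplot.cb_montecarlo <- function(object, ...) {
  dat <- object$summary
  dat$tf <- factor(dat$tf)
  dat$df <- factor(dat$df)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$tf, fill = .data$df)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$min, lower = .data$q1, middle = .data$median,
                   upper = .data$q3, ymax = .data$max),
      stat = "identity", position = ggplot2::position_dodge()) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::labs(x = "Timeframe (yr)",
                  y = "Relative C benefit of succession (%)",
                  fill = "DF") +
    ggplot2::theme_minimal()
}

#' @rdname cbenefit-plots
#' @method autoplot cb_scenario
#' @export
autoplot.cb_scenario <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$table[c("year", "cb_be", "cb_nsucc")],
                             cols = -"year", names_to = "option",
                             values_to = "cb")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$year, y = .data$cb,
                                    colour = .data$option)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Cumulative C benefit (tC/ha)",
                  colour = NULL,
                  title = sprintf("Scenario %s", object$spec$name)) +
    ggplot2::theme_minimal()
}
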