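#' Dynamic-DF scenario specifications
#'
#' A scenario pairs a calendar span with a time-varying DF schedule and a
#' growth-curve kind for the succession counterfactual. Two built-in
#' scenarios describe plausible decarbonization pathways for the displaced
#' energy mix: `scenario_high()` starts from coal/oil displacement in heat and
#' CHP (DF 0.7), falling to 0.55 by 2050 and 0.4 by 2100; `scenario_low()`
#' assumes natural-gas displacement is equally common from the start (0.55),
#' falling to 0.35 by 2050 and 0.25 by 2100. Intermediate years interpolate
#' linearly.
#'
#' @param name Scenario label.
#' @param schedule A [df_schedule()].
#' @param years Two-element calendar span (default 2020-2100).
#' @param growth_kind Growth-curve kind for the succession side.
#' @return A `cb_scenario_spec`.
#' @export
scenario_spec <- function(name, schedule, years = c(2020, 2100),
                          growth_kind = c("linear_capped", "logistic",
                                          "chapman_richards")) {
  stopifnot(inherits(schedule, "cb_df_schedule"))
  growth_kind <- match.arg(growth_kind)
  if (length(years) != 2 || years[2] <= years[1]) {
    abort("`years` must be an increasing two-element calendar span.",
          class = "cbenefit_validation_error")
  }
  structure(list(name = name, schedule = schedule,
                 years = as.numeric(years), growth_kind = growth_kind),
            class = "cb_scenario_spec")
}

#' @rdname scenario_spec
#' @export
scenario_high <- function(growth_kind = "linear_capped") {
  scenario_spec("HIGH", df_schedule(c(2020, 2050, 2100), c(0.7, 0.55, 0.4)),
                growth_kind = growth_kind)
}

#' @rdname scenario_spec
#' @export
scenario_low <- function(growth_kind = "linear_capped") {
  scenario_spec("LOW", df_schedule(c(2020, 2050, 2100), c(0.55, 0.35, 0.25)),
                growth_kind = growth_kind)
}

#' Run a dynamic-DF scenario
#'
#' Produces annual cumulative carbon benefit curves over the scenario's
#' calendar span: the bioenergy option accumulates pool changes plus
#' displacement at the schedule's (clamped, mid-year-evaluated) DF, and the
#' succession option accumulates pool changes under the chosen growth kind.
#'
#' @param spec A [scenario_spec()].
#' @param profile A `cb_region_profile`.
#' @param cat A `cb_catalog`.
#' @param params A [model_params()]; its `growth_kind` is overridden by the
#'   scenario's.
#' @return A `cb_scenario`: list with `table` (tibble `year`, `cb_be`,
#'   `cb_nsucc`, `df`), the spec and inputs.
#' @examples
#' \donttest{
#' sc <- run_scenario(scenario_low(), bundled_profile(), bundled_catalog())
#' tail(tidy(sc))
#' }
#' @export
run_scenario <- function(spec, profile, cat, params = model_params()) {
  stopifnot(inherits(spec, "cb_scenario_spec"))
  params$growth_kind <- spec$growth_kind
  if (spec$growth_kind == "chapman_richards" && is.null(params$cr_params)) {
    abort("Chapman-Richards growth needs `cr_params` in `params`.",
          class = "cbenefit_validation_error")
  }
  y0 <- spec$years[1]
  span <- spec$years[2] - spec$years[1]
  comp <- region_components(profile, cat, span, params)
  ser <- components_series(comp)

  mids <- y0 + seq_len(span) - 0.5
  dfs_mid <- df_at(spec$schedule, mids)
  disp <- c(0, cumsum(ser$harvest[-1] * (1 - params$l_supply) * dfs_mid))

  table <- tibble(
    year = y0 + comp$years,
    cb_be = ser$be_pools + disp,
    cb_nsucc = ser$cb_nsucc,
    df = df_at(spec$schedule, y0 + comp$years))

  structure(list(table = table, spec = spec, profile = profile,
                 params = params),
            class = "cb_scenario")
}

#' @export
print.cb_scenario <- function(x, ...) {
  cat(sprintf("<cb_scenario> '%s' (%g-%g), growth: %s\n",
              x$spec$name, x$spec$years[1], x$spec$years[2],
              x$spec$growth_kind))
  print(x$table, n = 10)
  invisible(x)
}
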