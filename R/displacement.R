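#' Displacement factor specification
#'
#' A displacement factor (DF) is the fossil carbon emission avoided per unit
#' of biomass carbon combusted, at equal final energy delivered. It is built
#' from a conversion route (bioenergy efficiency and its fossil counterpart)
#' and the combustion emission factors of the biomass and fossil fuels;
#' optionally upstream (supply-chain) emissions of both fuels enter an
#' extended form.
#'
#' The upstream case selects which tabulated upstream values are used:
#' `"favorable"` pairs best-case biomass supply with worst-case fossil supply
#' (maximizing DF), `"unfavorable"` the reverse, `"none"` ignores upstream
#' emissions.
#'
#' @param route One-row routes tibble (from [lookup_route()]) or a list with
#'   `eta_be`, `eta_fossil`, `electricity_share`.
#' @param biomass_fuel,fossil_fuel One-row fuels tibbles (from
#'   [lookup_fuel()]) or lists with `combustion_ef_kgCO2_GJ`,
#'   `upstream_best`, `upstream_worst`.
#' @param upstream_case One of `"none"`, `"favorable"`, `"unfavorable"`.
#' @return A `cb_displacement_spec`.
#' @export
displacement_spec <- function(route, biomass_fuel, fossil_fuel,
                              upstream_case = c("none", "favorable",
                                                "unfavorable")) {
  upstream_case <- match.arg(upstream_case)
  as_rec <- function(x) if (is.data.frame(x)) as.list(x[1, ]) else x
  route <- as_rec(route)
  biomass_fuel <- as_rec(biomass_fuel)
  fossil_fuel <- as_rec(fossil_fuel)
  check_number(route$eta_be, "eta_be", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(route$eta_fossil, "eta_fossil", lower = 0, upper = 1,
               strict_lower = TRUE)
  share <- route$electricity_share %||% 1
  check_number(share, "electricity_share", lower = 0, upper = 1,
               strict_lower = TRUE)
  route$electricity_share <- share
  for (f in list(biomass_fuel, fossil_fuel)) {
    check_number(f$combustion_ef_kgCO2_GJ, "combustion_ef_kgCO2_GJ",
                 lower = 0, strict_lower = TRUE)
  }
  structure(list(route = route, biomass_fuel = biomass_fuel,
                 fossil_fuel = fossil_fuel, upstream_case = upstream_case),
            class = "cb_displacement_spec")
}

#' Compute displacement factors
#'
#' `compute_df()` implements the basic form
#' `DF = (eta_BE / eta_fossil) * (CE_fossil / CE_BM)`: the efficiency ratio of
#' the bioenergy pathway to its fossil counterpart times the ratio of the
#' fuels' combustion emission factors. For CHP routes both efficiencies are
#' electricity-allocated with the route's `electricity_share` before the ratio
#' (the identical share cancels, mirroring an allocation applied to both
#' systems alike). `compute_df_upstream()` adds upstream emissions:
#' `DF = (eta_BE / eta_fossil) * (CE_fossil + UE_fossil) / CE_BM - UE_BM / CE_BM`,
#' which reduces exactly to the basic form at zero upstream emissions.
#' `df_for_spec()` dispatches on the spec's upstream case.
#'
#' Since DF is a ratio of emissions per energy, any consistent mass basis
#' (CO2 or C) for the emission factors cancels.
#'
#' @param spec A [displacement_spec()].
#' @param ue_fossil,ue_bm Upstream emissions of fossil fuel / biomass supply,
#'   kg CO2/GJ.
#' @return A single dimensionless DF.
#' @examples
#' spec <- displacement_spec(
#'   route = list(eta_be = 0.36, eta_fossil = 0.45, electricity_share = 1),
#'   biomass_fuel = list(combustion_ef_kgCO2_GJ = 112,
#'                       upstream_best = 0, upstream_worst = 0),
#'   fossil_fuel = list(combustion_ef_kgCO2_GJ = 96.1,
#'                      upstream_best = 0, upstream_worst = 0))
#' compute_df(spec)  # 0.6864
#' @export
compute_df <- function(spec) {
  stopifnot(inherits(spec, "cb_displacement_spec"))
  share <- spec$route$electricity_share
  eta_be <- spec$route$eta_be * share
  eta_fossil <- spec$route$eta_fossil * share
  if (eta_be <= 0 || eta_fossil <= 0) {
    abort("Conversion efficiencies must be positive.",
          class = "cbenefit_validation_error")
  }
  (eta_be / eta_fossil) *
    (spec$fossil_fuel$combustion_ef_kgCO2_GJ /
       spec$biomass_fuel$combustion_ef_kgCO2_GJ)
}

#' @rdname compute_df
#' @export
compute_df_upstream <- function(spec, ue_fossil, ue_bm) {
  stopifnot(inherits(spec, "cb_displacement_spec"))
  check_number(ue_fossil, "ue_fossil", lower = 0)
  check_number(ue_bm, "ue_bm", lower = 0)
  share <- spec$route$electricity_share
  eta_be <- spec$route$eta_be * share
  eta_fossil <- spec$route$eta_fossil * share
  if (eta_be <= 0 || eta_fossil <= 0) {
    abort("Conversion efficiencies must be positive.",
          class = "cbenefit_validation_error")
  }
  ce_bm <- spec$biomass_fuel$combustion_ef_kgCO2_GJ
  ce_fossil <- spec$fossil_fuel$combustion_ef_kgCO2_GJ
  (eta_be / eta_fossil) * ((ce_fossil + ue_fossil) / ce_bm) - ue_bm / ce_bm
}

#' @rdname compute_df
#' @export
df_for_spec <- function(spec) {
  switch(spec$upstream_case,
    none = compute_df(spec),
    favorable = compute_df_upstream(
      spec,
      ue_fossil = spec$fossil_fuel$upstream_worst,
      ue_bm = spec$biomass_fuel$upstream_best),
    unfavorable = compute_df_upstream(
      spec,
      ue_fossil = spec$fossil_fuel$upstream_best,
      ue_bm = spec$biomass_fuel$upstream_worst))
}

#' Tabulate DFs for every route x fossil fuel x upstream case
#'
#' Mirrors the familiar bar-chart decomposition of DF ranges by conversion
#' route and displaced fossil fuel, with and without upstream emissions.
#'
#' @param cat A `cb_catalog`.
#' @param biomass_fuel Name of the biomass fuel in the catalog (default
#'   `"wood_chips"`).
#' @param cases Character vector of upstream cases to include.
#' @return A tibble with `route`, `fossil_fuel`, `upstream_case`, `df`.
#' @export
df_table <- function(cat, biomass_fuel = "wood_chips",
                     cases = c("none", "favorable", "unfavorable")) {
  stopifnot(inherits(cat, "cb_catalog"))
  bm <- lookup_fuel(cat, biomass_fuel)
  fossils <- setdiff(cat$fuels$name, biomass_fuel)
  grid <- tidyr::expand_grid(route = cat$routes$name,
                             fossil_fuel = fossils,
                             upstream_case = cases)
  grid$df <- purrr::pmap_dbl(grid, function(route, fossil_fuel, upstream_case) {
    df_for_spec(displacement_spec(
      lookup_route(cat, route), bm, lookup_fuel(cat, fossil_fuel),
      upstream_case = upstream_case))
  })
  grid
}

#' Time-varying DF schedules
#'
#' A schedule anchors DF values at calendar years; intermediate years are
#' interpolated linearly and values outside the anchor range are clamped to
#' the first/last anchor (`df_at()`).
#'
#' @param years Strictly increasing anchor years.
#' @param dfs DF values at the anchors, each in \[0, 1.2\].
#' @return A `cb_df_schedule`.
#' @examples
#' sched <- df_schedule(c(2020, 2050), c(0.7, 0.55))
#' df_at(sched, 2035)  # 0.625
#' @export
df_schedule <- function(years, dfs) {
  if (length(years) != length(dfs) || length(years) < 1) {
    abort("`years` and `dfs` must be equal-length, non-empty vectors.",
          class = "cbenefit_validation_error")
  }
  if (length(years) > 1 && any(diff(years) <= 0)) {
    abort("Schedule anchor years must be strictly increasing.",
          class = "cbenefit_validation_error")
  }
  if (any(dfs < 0 | dfs > 1.2)) {
    abort("Schedule DF values must lie in [0, 1.2].",
          class = "cbenefit_validation_error")
  }
  structure(list(years = as.numeric(years), dfs = as.numeric(dfs)),
            class = "cb_df_schedule")
}

#' @rdname df_schedule
#' @param schedule A `cb_df_schedule`.
#' @param year Years at which to evaluate the schedule.
#' @export
df_at <- function(schedule, year) {
  stopifnot(inherits(schedule, "cb_df_schedule"))
  if (length(schedule$years) == 1) {
    return(rep(schedule$dfs, length(year)))
  }
  approx(schedule$years, schedule$dfs, xout = year, rule = 2)$y
}

#' Closed-form cumulative fossil-fuel displacement
#'
#' With constant DF and gradual conversion over TP years, cumulative displaced
#' fossil carbon over a timeframe TF is
#' `Y (1 - L_supply) (TF - TP/2) DF` (tC/ha): the average cohort loses TP/2
#' producing years to the staggered conversion. The time-resolved engine
#' ([displacement_series()]) reproduces this value exactly for constant DF.
#'
#' @param y Plant-gate yield Y, tC/ha/yr.
#' @param l_supply Supply-chain loss fraction.
#' @param tf Timeframe, years.
#' @param tp Transition period, years (`tf >= tp >= 0`).
#' @param df Displacement factor.
#' @return Cumulative displaced carbon, tC/ha.
#' @examples
#' cumulative_displacement(4, 0.1, 50, 10, 0.5)  # 81
#' @export
cumulative_displacement <- function(y, l_supply, tf, tp, df) {
  check_number(y, "y", lower = 0)
  check_number(l_supply, "l_supply", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(tp, "tp", lower = 0)
  check_number(tf, "tf", lower = 0)
  check_number(df, "df", lower = 0, upper = 1.2)
  if (tf < tp) {
    abort(sprintf("Timeframe (%g) must be at least the transition period (%g).",
                  tf, tp), class = "cbenefit_validation_error")
  }
  y * (1 - l_supply) * (tf - tp / 2) * df
}

#' Time-resolved cumulative displaced carbon
#'
#' Converts an annual harvest series into cumulative displaced fossil carbon:
#' each year's plant-gate harvest, reduced by supply-chain losses, displaces
#' fossil carbon at that year's DF. With a schedule, DF is evaluated at the
#' mid-point of each annual interval (consistent with the engine's mid-year
#' accounting); the series' calendar span must be covered by the anchors
#' unless `clamp = TRUE`, in which case end values are held.
#'
#' @param harvests A `cb_pool_trajectory` with a `harvest` column, or a
#'   numeric vector of harvests for years 1..TF.
#' @param l_supply Supply-chain loss fraction.
#' @param df A constant DF or a [df_schedule()].
#' @param start_year Calendar year corresponding to simulation year 0.
#' @param clamp Allow schedule evaluation outside the anchor range.
#' @return A tibble `year` (0..TF), `cb_fuel_disp` (cumulative tC/ha).
#' @export
displacement_series <- function(harvests, l_supply, df, start_year = 0,
                                clamp = FALSE) {
  if (inherits(harvests, "cb_pool_trajectory") || is.data.frame(harvests)) {
    if (!"harvest" %in% names(harvests)) {
      abort("`harvests` trajectory has no 'harvest' column (is it an SRC run?).",
            class = "cbenefit_validation_error")
    }
    h <- harvests$harvest[harvests$year >= 1][order(harvests$year[harvests$year >= 1])]
  } else {
    h <- as.numeric(harvests)
  }
  check_number(l_supply, "l_supply", lower = 0, upper = 1, strict_upper = TRUE)
  tf <- length(h)
  mids <- start_year + seq_len(tf) - 0.5
  if (inherits(df, "cb_df_schedule")) {
    if (!clamp && tf > 0 &&
        (min(mids) < min(df$years) || max(mids) > max(df$years))) {
      abort(sprintf(
        "DF schedule [%g, %g] does not cover the series span [%g, %g]; set clamp = TRUE to hold end values.",
        min(df$years), max(df$years), min(mids), max(mids)),
        class = "cbenefit_validation_error")
    }
    dfs <- df_at(df, mids)
  } else {
    check_number(df, "df", lower = 0, upper = 1.2)
    dfs <- rep(df, tf)
  }
  tibble(year = 0:tf,
         cb_fuel_disp = c(0, cumsum(h * (1 - l_supply) * dfs)))
}
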