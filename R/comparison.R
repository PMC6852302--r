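#' Model parameter settings
#'
#' Bundles the tunable parameters shared by the comparison, Monte Carlo and
#' scenario drivers. Defaults are the model's stated world: a 10-year
#' transition period, linear-capped Tier 1 growth with a 3-year slow start at
#' one third of the zone rate, 20% on-site and 10% supply-chain losses,
#' 4-year coppice rotation, SRC root-to-shoot ratio 0.3, litter decay 0.35/yr,
#' and 20-year linear transitions of litter and soil stocks.
#'
#' @param tp Transition period, years.
#' @param growth_kind One of `"linear_capped"`, `"logistic"`,
#'   `"chapman_richards"`.
#' @param l_onsite On-site aboveground loss fraction of SRC.
#' @param l_supply Supply-chain loss fraction.
#' @param rotation Coppice rotation, years.
#' @param root_to_shoot_src SRC belowground:aboveground ratio.
#' @param litter_decay_k SRC litter decay rate, 1/yr.
#' @param slow_years,slow_factor Slow-start phase of natural regrowth.
#' @param dom_ramp_years,soc_ramp_years Tier 1 transition lengths for litter
#'   and soil stocks.
#' @param cr_params Optional tibble (`eco_zone`, `a`, `b`, `k`, `m`) of
#'   Chapman-Richards parameters, required when
#'   `growth_kind = "chapman_richards"`.
#' @return A `cb_model_params` list.
#' @export
model_params <- function(tp = 10, growth_kind = c("linear_capped", "logistic",
                                                  "chapman_richards"),
                         l_onsite = 0.20, l_supply = 0.10, rotation = 4,
                         root_to_shoot_src = 0.30, litter_decay_k = 0.35,
                         slow_years = 3, slow_factor = 1 / 3,
                         dom_ramp_years = 20, soc_ramp_years = 20,
                         cr_params = NULL) {
  growth_kind <- match.arg(growth_kind)
  check_number(tp, "tp", lower = 1)
  check_number(l_onsite, "l_onsite", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(l_supply, "l_supply", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(rotation, "rotation", lower = 1)
  if (growth_kind == "chapman_richards" && is.null(cr_params)) {
    abort("Chapman-Richards growth needs `cr_params` (eco_zone, a, b, k, m).",
          class = "cbenefit_validation_error")
  }
  structure(list(tp = as.integer(tp), growth_kind = growth_kind,
                 l_onsite = l_onsite, l_supply = l_supply,
                 rotation = rotation, root_to_shoot_src = root_to_shoot_src,
                 litter_decay_k = litter_decay_k,
                 slow_years = slow_years, slow_factor = slow_factor,
                 dom_ramp_years = dom_ramp_years,
                 soc_ramp_years = soc_ramp_years,
                 cr_params = cr_params),
            class = "cb_model_params")
}

growth_curve_for_zone <- function(zone, params, tf_max) {
  lin <- linear_growth(rate = zone$growth_rate_tC_ha_yr,
                       cap = zone$agb_max_tC_ha,
                       slow_years = params$slow_years,
                       slow_factor = params$slow_factor)
  switch(params$growth_kind,
    linear_capped = lin,
    logistic = fit_logistic(
      lin, horizon = max(tf_max, ceiling(1.5 * lin$time_to_cap))),
    chapman_richards = {
      hit <- params$cr_params[params$cr_params$eco_zone == zone$eco_zone, ]
      if (nrow(hit) != 1) {
        abort(sprintf("No Chapman-Richards parameters for eco zone '%s'.",
                      zone$eco_zone), class = "cbenefit_validation_error")
      }
      chapman_richards(hit$a, hit$b, hit$k, hit$m)
    })
}

# Precomputes everything that does not depend on the SRC yield scalers
# (npp multiplier, l_onsite): the natural-succession side in full, and the
# SRC side as unit-response vectors over years 0..tf_max:
#   s1[t]: standing-stock structure per unit Y (tranche-weighted age mod R)
#   d1[t]: litter structure per unit litter input I
#   e1[t]: cumulative converted-area-years (per-unit-Y cumulative production)
# all already weighted by stratum npp_pot, so an option's pools are scalar
# multiples m(1-l_onsite) resp. m*l_onsite of these. Both the deterministic
# comparison and every Monte Carlo draw are assembled from this one object,
# so degenerate draws reproduce the deterministic result bit-for-bit.
region_components <- function(profile, cat, tf_max, params) {
  stopifnot(inherits(profile, "cb_region_profile"),
            inherits(cat, "cb_catalog"),
            inherits(params, "cb_model_params"))
  check_profile(profile, cat)
  if (tf_max < params$tp) {
    abort(sprintf("Timeframe (%g) must be at least the transition period (%d).",
                  tf_max, params$tp), class = "cbenefit_validation_error")
  }
  sched <- conversion_schedule(params$tp)
  years <- 0:tf_max
  ages <- pmax(tranche_ages(years, sched), 0)

  n <- nrow(profile)
  w <- profile$weight
  bm_n <- dom_n <- soc <- numeric(length(years))
  soc0_parts <- numeric(n)
  bm_below_n <- numeric(length(years))
  for (i in seq_len(n)) {
    zone <- as.list(lookup_zone(cat, profile$eco_zone[i],
                                profile$climate_zone[i], profile$soil_type[i]))
    fac <- lookup_factors(cat, profile$tillage_class[i])
    curve <- growth_curve_for_zone(zone, params, tf_max)
    bm_i <- as.vector(growth_value(curve, ages) %*% sched$weights)
    dom_i <- as.vector((zone$litter_default_tC_ha *
                          pmin(ages / params$dom_ramp_years, 1)) %*%
                         sched$weights)
    soc_i <- soc_trajectory(zone$soc_ref_tC_ha, fac, tf_max,
                            params$soc_ramp_years)$soc
    bm_n <- bm_n + w[i] * bm_i
    bm_below_n <- bm_below_n + w[i] * zone$root_to_shoot * bm_i
    dom_n <- dom_n + w[i] * dom_i
    soc <- soc + w[i] * soc_i
  }

  npp_agg <- sum(w * profile$npp_pot)
  k <- params$litter_decay_k
  e1_raw <- as.vector(ages %*% sched$weights)         # area-years per ha
  s1_raw <- as.vector((ages %% params$rotation) %*% sched$weights)
  d1_raw <- as.vector((1 - exp(-k * ages)) %*% sched$weights) / k

  list(years = years, tf_max = tf_max, params = params,
       profile = profile, npp_agg = npp_agg,
       nsucc = list(bm_above = bm_n, bm_below = bm_below_n, dom = dom_n,
                    soc = soc),
       src = list(s1 = npp_agg * s1_raw, d1 = npp_agg * d1_raw,
                  e1 = npp_agg * e1_raw, soc = soc))
}

# Per-option cumulative pool deltas (relative to year 0) over all years.
components_series <- function(comp, m = 1, l_onsite = NULL) {
  p <- comp$params
  l_onsite <- l_onsite %||% p$l_onsite
  y_scale <- m * (1 - l_onsite)   # plant-gate yield per unit npp_agg
  i_scale <- m * l_onsite         # litter input per unit npp_agg
  dsoc <- comp$nsucc$soc - comp$nsucc$soc[1]
  cbn <- comp$nsucc$bm_above + comp$nsucc$bm_below + comp$nsucc$dom + dsoc
  src_above <- y_scale * comp$src$s1
  src_pools <- (1 + p$root_to_shoot_src) * src_above +
    i_scale * comp$src$d1 + dsoc
  disp1 <- y_scale * (1 - p$l_supply) * comp$src$e1  # displacement per unit DF
  list(cb_nsucc = cbn, be_pools = src_pools, disp_per_df = disp1,
       dsoc = dsoc, src_above = src_above,
       harvest = y_scale * c(0, diff(comp$src$e1)))
}

#' Cumulative carbon benefit of natural succession
#'
#' The total change in carbon stocks between year 0 and the timeframe's end:
#' the sum over the four pools (aboveground biomass, belowground biomass,
#' dead organic matter, soil) of pool(tf) - pool(0).
#'
#' @param traj A `cb_pool_trajectory` (either option works; only stock columns
#'   are summed).
#' @param tf Timeframe, years (must be covered by the trajectory).
#' @return Cumulative benefit, tC/ha.
#' @export
cb_nsucc <- function(traj, tf) {
  deltas <- pool_deltas(traj, tf)
  sum(deltas)
}

pool_deltas <- function(traj, tf) {
  stopifnot(is.data.frame(traj))
  if (!tf %in% traj$year) {
    abort(sprintf("Timeframe %g is outside the trajectory (years 0..%d).",
                  tf, max(traj$year)), class = "cbenefit_validation_error")
  }
  pools <- c("bm_above", "bm_below", "dom", "soc")
  at <- function(t) vapply(pools, function(p) traj[[p]][traj$year == t],
                           numeric(1))
  at(tf) - at(0)
}

#' Cumulative carbon benefit of SRC bioenergy
#'
#' Carbon stock changes of the plantation plus cumulative displaced fossil
#' carbon: the sum of the four pool deltas and the displacement series at the
#' timeframe's end.
#'
#' @param traj A `cb_pool_trajectory` of the SRC option.
#' @param disp A displacement series from [displacement_series()].
#' @param tf Timeframe, years.
#' @return Cumulative benefit, tC/ha.
#' @export
cb_be <- function(traj, disp, tf) {
  deltas <- pool_deltas(traj, tf)
  if (!tf %in% disp$year) {
    abort(sprintf("Timeframe %g is outside the displacement series.", tf),
          class = "cbenefit_validation_error")
  }
  sum(deltas) + disp$cb_fuel_disp[disp$year == tf]
}

#' Relative carbon benefit of succession over bioenergy
#'
#' `100 * cb_nsucc / cb_be`, in percent. Ratios above 100% mean natural
#' succession is the superior option. Undefined (NA, with a warning) when the
#' bioenergy benefit is zero.
#'
#' @param cb_nsucc,cb_be Cumulative benefits, tC/ha.
#' @return Percentage (possibly vectorized).
#' @export
relative_benefit <- function(cb_nsucc, cb_be) {
  out <- 100 * cb_nsucc / cb_be
  if (any(cb_be == 0)) {
    warn("Relative benefit undefined where cb_be = 0; reported as NA.")
    out[cb_be == 0] <- NA_real_
  }
  out
}

#' Compare natural succession with SRC bioenergy over a tf x DF grid
#'
#' The package's main driver: builds per-stratum pool trajectories for both
#' land-use options, aggregates them with the profile's area weights, and
#' evaluates the cumulative carbon benefits, their ratio and the per-pool
#' breakdown for every combination of timeframe and displacement factor.
#'
#' @param profile A `cb_region_profile`.
#' @param cat A `cb_catalog`.
#' @param timeframes Integer years (default 20, 30, 40, 50, 70, 100).
#' @param dfs Displacement factors (default 0.1 to 1 in steps of 0.1).
#' @param params A [model_params()].
#' @return A `cb_comparison`: list with `table` (tibble `tf`, `df`,
#'   `cb_nsucc`, `cb_be`, `ratio_pct`), `pools` (per-pool deltas by tf and
#'   option), `trajectories` (aggregated annual pool tables) and the inputs.
#' @examples
#' \donttest{
#' cmp <- compare_options(bundled_profile(), bundled_catalog())
#' head(tidy(cmp))
#' }
#' @export
compare_options <- function(profile, cat,
                            timeframes = c(20, 30, 40, 50, 70, 100),
                            dfs = seq(0.1, 1, by = 0.1),
                            params = model_params()) {
  if (length(timeframes) == 0 || length(dfs) == 0) {
    abort("`timeframes` and `dfs` must be non-empty.",
          class = "cbenefit_validation_error")
  }
  tf_max <- max(timeframes)
  comp <- region_components(profile, cat, tf_max, params)
  ser <- components_series(comp)

  grid <- tidyr::expand_grid(tf = sort(unique(timeframes)),
                             df = sort(unique(dfs)))
  idx <- grid$tf + 1L
  grid$cb_nsucc <- ser$cb_nsucc[idx]
  grid$cb_be <- ser$be_pools[idx] + grid$df * ser$disp_per_df[idx]
  grid$ratio_pct <- relative_benefit(grid$cb_nsucc, grid$cb_be)

  p <- comp$params
  tfs <- sort(unique(timeframes))
  ti <- tfs + 1L
  pools <- tibble(
    tf = tfs,
    d_bm_above_nsucc = comp$nsucc$bm_above[ti],
    d_bm_below_nsucc = comp$nsucc$bm_below[ti],
    d_dom_nsucc = comp$nsucc$dom[ti],
    d_soc = ser$dsoc[ti],
    d_bm_above_be = ser$src_above[ti],
    d_bm_below_be = p$root_to_shoot_src * ser$src_above[ti],
    d_dom_be = p$l_onsite * comp$src$d1[ti],
    disp_per_df = ser$disp_per_df[ti])

  trajectories <- list(
    nsucc = new_pool_trajectory(
      tibble(year = comp$years,
             bm_above = comp$nsucc$bm_above,
             bm_below = comp$nsucc$bm_below,
             dom = comp$nsucc$dom,
             soc = comp$nsucc$soc),
      option = "nSucc"),
    src = new_pool_trajectory(
      tibble(year = comp$years,
             bm_above = ser$src_above,
             bm_below = p$root_to_shoot_src * ser$src_above,
             dom = p$l_onsite * comp$src$d1,
             soc = comp$src$soc,
             harvest = ser$harvest),
      option = "SRC"))

  structure(list(table = grid, pools = pools, trajectories = trajectories,
                 profile = profile, params = params,
                 timeframes = sort(unique(timeframes)),
                 dfs = sort(unique(dfs))),
            class = "cb_comparison")
}

#' @export
print.cb_comparison <- function(x, ...) {
  cat(sprintf("<cb_comparison> profile '%s': %d timeframes x %d DFs\n",
              profile_name(x$profile), length(x$timeframes), length(x$dfs)))
  print(x$table, n = 10)
  invisible(x)
}

#' Carbon parity time of bioenergy
#'
#' The smallest integer timeframe from which the bioenergy option's
#' cumulative carbon benefit stays at or above that of natural succession
#' through the search horizon, scanning annual model output; `NA` if the
#' bioenergy option is still behind at the horizon. The "sustained" reading
#' matters because SRC grows faster than natural regrowth in the first years,
#' so its benefit curve typically starts above, dips below at low DF, and
#' recrosses later — the recrossing is the policy-relevant parity point.
#' When bioenergy is ahead at every scanned year the parity time is 1.
#'
#' @param profile A `cb_region_profile`.
#' @param cat A `cb_catalog`.
#' @param df Constant displacement factor.
#' @param search_horizon Last timeframe scanned (default 200).
#' @param params A [model_params()].
#' @return Integer year or `NA_integer_`.
#' @export
parity_time <- function(profile, cat, df, search_horizon = 200,
                        params = model_params()) {
  check_number(df, "df", lower = 0, upper = 1.2)
  check_number(search_horizon, "search_horizon", lower = 1)
  comp <- region_components(profile, cat, search_horizon, params)
  ser <- components_series(comp)
  cbb <- ser$be_pools + df * ser$disp_per_df
  parity_scan(ser$cb_nsucc[-1], cbb[-1])
}

# annual scan over years 1..length(cbn): first year from which the bioenergy
# benefit stays >= the succession benefit
parity_scan <- function(cbn, cbb) {
  behind <- which(cbb < cbn)
  if (length(behind) == 0) return(1L)
  if (max(behind) >= length(cbn)) return(NA_integer_)
  as.integer(max(behind) + 1L)
}

#' Break-even displacement factor
#'
#' Inverts the constant-DF benefit comparison at a given timeframe: the DF at
#' which both options yield equal cumulative benefits,
#' `DF* = (cb_nsucc - pool deltas of BE) / (Y (1 - l_supply) (tf - tp/2))`,
#' clipped at zero. Plugging DF* back reproduces a 100% benefit ratio.
#'
#' @param profile A `cb_region_profile`.
#' @param cat A `cb_catalog`.
#' @param tf Timeframe, years.
#' @param params A [model_params()].
#' @return The break-even DF (dimensionless, >= 0).
#' @export
crossover_df <- function(profile, cat, tf, params = model_params()) {
  check_number(tf, "tf", lower = 1)
  comp <- region_components(profile, cat, tf, params)
  ser <- components_series(comp)
  idx <- tf + 1L
  denom <- ser$disp_per_df[idx]
  if (denom == 0) {
    abort("Zero cumulative production: break-even DF undefined.",
          class = "cbenefit_validation_error")
  }
  max(0, (ser$cb_nsucc[idx] - ser$be_pools[idx]) / denom)
}
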