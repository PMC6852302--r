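#' Gradual land conversion schedule
#'
#' Cropland is converted in `tp` equal annual tranches (age cohorts); tranche
#' i (i = 0..tp-1) converts the fraction 1/tp of the area at the mid-year
#' instant i + 0.5. The mid-year convention makes the closed-form displacement
#' Y (1 - L) (TF - TP/2) DF an exact identity of the time-resolved engine.
#'
#' @param tp Transition period in years (default 10; the sensitivity
#'   alternative is 20; `tp = 1` is near-immediate conversion).
#' @return A `cb_schedule`: list with `tp`, tranche `times` and `weights`.
#' @export
conversion_schedule <- function(tp = 10) {
  check_number(tp, "tp", lower = 1)
  tp <- as.integer(tp)
  structure(list(tp = tp,
                 times = seq_len(tp) - 0.5,
                 weights = rep(1 / tp, tp)),
            class = "cb_schedule")
}

#' SRC plantation configuration
#'
#' Short rotation coppice stands are parameterized by the site's potential net
#' primary production and loss fractions: the plant-gate yield is
#' `Y = npp_pot (1 - l_onsite)` (on-site losses through herbivory, leaf
#' shedding etc. default to 20%); a further `l_supply` (default 10%) is lost
#' along the wood-chip supply chain and is applied only when converting
#' harvests into displaced fossil carbon, never to standing stocks.
#'
#' @param npp_pot Potential net primary production, tC/ha/yr.
#' @param l_onsite On-site aboveground loss fraction (default 0.20).
#' @param l_supply Supply-chain loss fraction (default 0.10).
#' @param rotation Coppice rotation length in years (default 4; SRC is
#'   typically harvested every 2-5 years).
#' @param root_to_shoot Belowground:aboveground biomass ratio (default 0.30).
#' @param litter_decay_k First-order litter decay rate, 1/yr (default 0.35);
#'   on-site losses feed the litter pool, which accumulates towards I/k.
#' @return A `cb_src_config` list.
#' @export
src_config <- function(npp_pot, l_onsite = 0.20, l_supply = 0.10,
                       rotation = 4, root_to_shoot = 0.30,
                       litter_decay_k = 0.35) {
  check_number(npp_pot, "npp_pot", lower = 0, strict_lower = TRUE)
  check_number(l_onsite, "l_onsite", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(l_supply, "l_supply", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(rotation, "rotation", lower = 1)
  check_number(root_to_shoot, "root_to_shoot", lower = 0, upper = 2)
  check_number(litter_decay_k, "litter_decay_k", lower = 0, strict_lower = TRUE)
  structure(list(npp_pot = npp_pot, l_onsite = l_onsite, l_supply = l_supply,
                 rotation = rotation, root_to_shoot = root_to_shoot,
                 litter_decay_k = litter_decay_k),
            class = "cb_src_config")
}

new_pool_trajectory <- function(df, option) {
  structure(df, option = option,
            class = c("cb_pool_trajectory", class(df)))
}

#' @export
print.cb_pool_trajectory <- function(x, ...) {
  cat(sprintf("<cb_pool_trajectory> option: %s, years 0..%d\n",
              attr(x, "option"), max(x$year)))
  NextMethod()
}

factors_product <- function(factors) {
  if (is.data.frame(factors)) factors <- as.list(factors[1, ])
  check_number(factors$f_lu, "f_lu", lower = 0, strict_lower = TRUE)
  check_number(factors$f_mg, "f_mg", lower = 0, strict_lower = TRUE)
  check_number(factors$f_i, "f_i", lower = 0, strict_lower = TRUE)
  factors$f_lu * factors$f_mg * factors$f_i
}

#' Soil organic carbon trajectory under Tier 1 stock-change accounting
#'
#' Cropland SOC is the climate/soil reference stock multiplied by the relative
#' stock-change factors (land use x management x input). After conversion to
#' natural vegetation or plantation all factors are 1, and the stock moves
#' linearly from the cropland level to the reference level over `ramp_years`
#' (Tier 1: 20 years), then stays constant. The trajectory is identical for
#' both land-use options, so SOC cancels in their comparison.
#'
#' @param soc_ref Reference SOC stock, tC/ha.
#' @param factors Stock-change factors: a one-row tibble or list with `f_lu`,
#'   `f_mg`, `f_i`.
#' @param tf Timeframe in years.
#' @param ramp_years Transition length (default 20).
#' @return A tibble with columns `year` (0..tf) and `soc` (tC/ha).
#' @examples
#' f <- list(f_lu = 0.69, f_mg = 1, f_i = 1)
#' soc_trajectory(50, f, 25)  # 34.5 at year 0, 50 from year 20 on
#' @export
soc_trajectory <- function(soc_ref, factors, tf, ramp_years = 20) {
  check_number(soc_ref, "soc_ref", lower = 0, strict_lower = TRUE)
  check_number(tf, "tf", lower = 1)
  fp <- factors_product(factors)
  years <- 0:tf
  soc0 <- soc_ref * fp
  soc <- soc0 + (soc_ref - soc0) * pmin(years, ramp_years) / ramp_years
  tibble(year = years, soc = soc)
}

# age of each tranche at each reporting year: years x tranches matrix
tranche_ages <- function(years, schedule) {
  outer(years, schedule$times, `-`)
}

#' Carbon pool trajectory under natural succession
#'
#' Each tranche converted at mid-year instant tau accumulates aboveground
#' biomass along the growth curve evaluated at its stand age, belowground
#' biomass as `root_to_shoot` times aboveground, and litter (DOM) ramping
#' linearly from zero to the zone's mature litter stock over `dom_ramp_years`
#' (Tier 1: 20) since conversion. Pool totals are tranche-weighted sums,
#' reported at integer years. SOC follows [soc_trajectory()] region-wide from
#' year 0 (a convention that cancels between options; see the vignette).
#'
#' @param zone One-row zones tibble from [lookup_zone()] (or a list with the
#'   same fields).
#' @param curve A `cb_growth_curve` for the zone.
#' @param factors Stock-change factors (see [soc_trajectory()]).
#' @param schedule A [conversion_schedule()].
#' @param tf Timeframe, years; must be >= the transition period.
#' @param dom_ramp_years Litter ramp length (default 20).
#' @param soc_ramp_years SOC ramp length (default 20).
#' @return A `cb_pool_trajectory` tibble: `year`, `bm_above`, `bm_below`,
#'   `dom`, `soc` (all tC/ha).
#' @export
nsucc_trajectory <- function(zone, curve, factors, schedule = conversion_schedule(),
                             tf = 100, dom_ramp_years = 20, soc_ramp_years = 20) {
  if (is.data.frame(zone)) zone <- as.list(zone[1, ])
  check_number(tf, "tf", lower = 1)
  if (tf < schedule$tp) {
    abort(sprintf("Timeframe (%g) must be at least the transition period (%d).",
                  tf, schedule$tp), class = "cbenefit_validation_error")
  }
  years <- 0:tf
  ages <- pmax(tranche_ages(years, schedule), 0)
  bm_above <- as.vector(growth_value(curve, ages) %*% schedule$weights)
  dom <- as.vector((zone$litter_default_tC_ha *
                      pmin(ages / dom_ramp_years, 1)) %*% schedule$weights)
  soc <- soc_trajectory(zone$soc_ref_tC_ha, factors, tf, soc_ramp_years)$soc
  new_pool_trajectory(
    tibble(year = years,
           bm_above = bm_above,
           bm_below = zone$root_to_shoot * bm_above,
           dom = dom,
           soc = soc),
    option = "nSucc")
}

#' Carbon pool trajectory and harvests of an SRC plantation
#'
#' Per cohort, aboveground biomass grows at the on-site yield
#' `Y = npp_pot (1 - l_onsite)` per year since planting or the last coppice
#' and is cut back to zero at every rotation boundary, giving the classic
#' per-cohort sawtooth; with staggered cohorts the aggregate stock is constant
#' once every cohort is established. On-site losses `I = npp_pot * l_onsite`
#' feed the litter pool, which follows first-order accumulation
#' `(I/k)(1 - e^(-k age))`. SOC is identical to the succession option.
#'
#' The `harvest` column is the annual plant-gate yield flux (tC/ha/yr,
#' before supply-chain losses): with the mid-year cohort convention, its
#' cumulative sum over 0..TF equals `Y (TF - TP/2)` exactly, which is what the
#' closed-form displacement expression integrates. The discrete coppice
#' events themselves obey the mass balance cumulative growth = harvests +
#' standing stock; see the vignette for the bookkeeping conventions.
#'
#' @param cfg A [src_config()].
#' @param factors Stock-change factors (see [soc_trajectory()]).
#' @param soc_ref Reference SOC stock, tC/ha.
#' @param schedule A [conversion_schedule()].
#' @param tf Timeframe, years.
#' @param soc_ramp_years SOC ramp length (default 20).
#' @return A `cb_pool_trajectory` tibble: `year`, `bm_above`, `bm_below`,
#'   `dom`, `soc`, `harvest`.
#' @export
src_trajectory <- function(cfg, factors, soc_ref, schedule = conversion_schedule(),
                           tf = 100, soc_ramp_years = 20) {
  stopifnot(inherits(cfg, "cb_src_config"))
  check_number(tf, "tf", lower = 1)
  if (tf < schedule$tp) {
    abort(sprintf("Timeframe (%g) must be at least the transition period (%d).",
                  tf, schedule$tp), class = "cbenefit_validation_error")
  }
  if (cfg$rotation > tf) {
    abort(sprintf("Rotation (%g) exceeds the timeframe (%g).", cfg$rotation, tf),
          class = "cbenefit_validation_error")
  }
  years <- 0:tf
  y_onsite <- cfg$npp_pot * (1 - cfg$l_onsite)
  litter_in <- cfg$npp_pot * cfg$l_onsite
  k <- cfg$litter_decay_k
  ages <- pmax(tranche_ages(years, schedule), 0)

  bm_above <- y_onsite * as.vector((ages %% cfg$rotation) %*% schedule$weights)
  dom <- (litter_in / k) * as.vector((1 - exp(-k * ages)) %*% schedule$weights)
  # plant-gate production flux: converted-area-years accrued within each year
  harvest <- y_onsite * c(0, diff(as.vector(ages %*% schedule$weights)))
  soc <- soc_trajectory(soc_ref, factors, tf, soc_ramp_years)$soc

  new_pool_trajectory(
    tibble(year = years,
           bm_above = bm_above,
           bm_below = cfg$root_to_shoot * bm_above,
           dom = dom,
           soc = soc,
           harvest = harvest),
    option = "SRC")
}

#' Write a pool trajectory as a delimited table
#'
#' @param traj A `cb_pool_trajectory`.
#' @param path Output `.csv` or `.tsv` path.
#' @export
write_trajectory <- function(traj, path) {
  out <- as_tibble(as.data.frame(traj))
  if (tolower(tools::file_ext(path)) == "tsv") {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}
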