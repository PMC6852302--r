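# Independent brute-force oracles and in-code fixtures.
# The oracles deliberately use explicit per-cohort, per-year loops (and
# half-year stepping for the coppice sawtooth) instead of the package's
# vectorized closed forms.

tiny_zones <- function() {
  tibble::tibble(
    eco_zone = c("tropical_rainforest", "temperate_oceanic_forest", "desert"),
    climate_zone = c("tropical_wet", "cool_temperate_moist", "tropical_dry"),
    soil_type = c("high_activity_clay", "high_activity_clay", "sandy"),
    growth_rate_tC_ha_yr = c(3, 1.5, 0.047),
    agb_max_tC_ha = c(140, 70, 0.94),
    root_to_shoot = c(0.22, 0.30, 0.40),
    litter_default_tC_ha = c(5, 13, 0.5),
    soc_ref_tC_ha = c(60, 85, 20))
}

tiny_catalog <- function(zones = tiny_zones()) {
  catalog(
    zones = zones,
    factors = tibble::tibble(
      tillage_class = c("full_till", "no_till"),
      f_lu = 0.71, f_mg = c(1, 1.15), f_i = 1),
    fuels = tibble::tibble(
      name = c("wood_chips", "hard_coal", "natural_gas"),
      combustion_ef_kgCO2_GJ = c(112, 94.6, 56.1),
      upstream_best = c(1.5, 4, 4.5),
      upstream_worst = c(12, 16, 20)),
    routes = tibble::tibble(
      name = c("heat_boiler", "chp"),
      eta_be = c(0.85, 0.28), eta_fossil = c(0.9, 0.4),
      electricity_share = c(1, 0.6)))
}

tiny_profile <- function(weights = c(0.5, 0.3, 0.2),
                         npp = c(6.5, 4.5, 1.5)) {
  z <- tiny_zones()
  region_profile(tibble::tibble(
    eco_zone = z$eco_zone, climate_zone = z$climate_zone,
    soil_type = z$soil_type,
    tillage_class = c("full_till", "no_till", "full_till"),
    weight = weights, npp_pot = npp), name = "tiny")
}

# Brute-force SRC cohort engine: half-year time steps, explicit growth
# increments and coppice events. Returns aggregate stocks at integer years
# plus cumulative discretely-coppiced carbon and cumulative gross growth.
oracle_src_cohort <- function(npp, l_onsite, tp, rotation, tf,
                              root_to_shoot = 0.3, k = 0.35) {
  y <- npp * (1 - l_onsite)
  litter_in <- npp * l_onsite
  w <- 1 / tp
  bm <- dom <- numeric(tf + 1)
  coppiced_cum <- numeric(tf + 1)
  growth_cum <- numeric(tf + 1)
  for (i in 0:(tp - 1)) {
    tau <- i + 0.5
    stock <- 0
    grown <- 0
    harvested <- 0
    for (s in seq(0.5, tf, by = 0.5)) {
      if (s > tau) {
        stock <- stock + y * 0.5
        grown <- grown + y * 0.5
        age <- s - tau
        if (age %% rotation == 0) {
          harvested <- harvested + stock
          stock <- 0
        }
      }
      if (s %% 1 == 0) {
        t <- as.integer(s)
        bm[t + 1] <- bm[t + 1] + w * stock
        coppiced_cum[t + 1] <- coppiced_cum[t + 1] + w * harvested
        growth_cum[t + 1] <- growth_cum[t + 1] + w * grown
        age <- s - tau
        if (age > 0) {
          dom[t + 1] <- dom[t + 1] +
            w * (litter_in / k) * (1 - exp(-k * age))
        }
      }
    }
  }
  tibble::tibble(year = 0:tf, bm_above = bm,
                 bm_below = root_to_shoot * bm, dom = dom,
                 coppiced_cum = coppiced_cum, growth_cum = growth_cum)
}

# Brute-force natural-succession cohort engine: explicit loops over cohorts
# and reporting years, evaluating an arbitrary age->stock function.
oracle_nsucc_cohort <- function(value_fun, tp, tf, root_to_shoot,
                                litter_default, dom_ramp = 20) {
  w <- 1 / tp
  bm <- dom <- numeric(tf + 1)
  for (i in 0:(tp - 1)) {
    tau <- i + 0.5
    for (t in 0:tf) {
      age <- t - tau
      if (age > 0) {
        bm[t + 1] <- bm[t + 1] + w * value_fun(age)
        dom[t + 1] <- dom[t + 1] + w * litter_default * min(age / dom_ramp, 1)
      }
    }
  }
  tibble::tibble(year = 0:tf, bm_above = bm,
                 bm_below = root_to_shoot * bm, dom = dom)
}

# Annual incremental simulation of the linear-capped curve.
oracle_linear_incremental <- function(rate, cap, slow_years, slow_factor, tf) {
  stock <- numeric(tf + 1)
  for (t in seq_len(tf)) {
    inc <- if (t <= slow_years) rate * slow_factor else rate
    stock[t + 1] <- min(cap, stock[t] + inc)
  }
  stock
}

# Grid-search least squares for the constrained logistic fit (same K
# constraint as the package, independent optimizer).
oracle_logistic_grid <- function(curve, horizon,
                                 r_grid = exp(seq(log(0.01), log(2), length.out = 80)),
                                 t0_grid = seq(0, horizon, length.out = 80)) {
  cap <- curve$params$cap
  ts <- seq(0, horizon, by = 1)
  target <- growth_value(curve, ts)
  best <- list(sse = Inf)
  for (r in r_grid) {
    for (t0 in t0_grid) {
      denom <- stats::plogis(r * (horizon - t0)) - stats::plogis(-r * t0)
      if (denom <= 0) next
      K <- cap / denom
      f <- K * (stats::plogis(r * (ts - t0)) - stats::plogis(-r * t0))
      sse <- sum((f - target)^2)
      if (sse < best$sse) best <- list(sse = sse, r = r, t0 = t0, K = K)
    }
  }
  best
}
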