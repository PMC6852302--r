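full_till <- list(f_lu = 0.69, f_mg = 1, f_i = 1)

test_that("soil carbon follows the 20-year Tier 1 ramp", {
  s <- soc_trajectory(50, full_till, 30)
  expect_equal(s$soc[s$year == 0], 34.5)
  expect_equal(s$soc[s$year == 10], 42.25)
  expect_true(all(s$soc[s$year >= 20] == 50))

  # stock-change factors of 1 leave the soil untouched
  s1 <- soc_trajectory(50, list(f_lu = 1, f_mg = 1, f_i = 1), 30)
  expect_true(all(s1$soc == 50))
})

test_that("succession pools follow the tranche-weighted cohort sum", {
  zone <- as.list(lookup_zone(tiny_catalog(), "tropical_rainforest",
                              "tropical_wet", "high_activity_clay"))
  zone$root_to_shoot <- 0.25
  cv <- linear_growth(3, 90)

  # near-immediate conversion: belowground is proportional to aboveground
  tr1 <- nsucc_trajectory(zone, cv, full_till, conversion_schedule(1), tf = 40)
  expect_equal(tr1$bm_below[tr1$year == 10] / tr1$bm_above[tr1$year == 10],
               0.25)
  expect_equal(tr1$bm_above[1], 0)
  expect_equal(tr1$dom[1], 0)
  expect_true(all(diff(tr1$bm_above) >= -1e-12))

  # 10-year transition: explicit cohort-sum formula
  tr10 <- nsucc_trajectory(zone, cv, full_till, conversion_schedule(10), tf = 60)
  for (t in c(10, 25, 60)) {
    expect_equal(tr10$bm_above[tr10$year == t],
                 mean(growth_value(cv, t - (0:9) - 0.5)),
                 tolerance = 1e-12)
  }

  # litter ramp with mid-year offset: tranche age 9.5 of a 20-year ramp
  zone13 <- zone
  zone13$litter_default_tC_ha <- 13
  trd <- nsucc_trajectory(zone13, cv, full_till, conversion_schedule(1), tf = 30)
  expect_equal(trd$dom[trd$year == 10], 13 * 9.5 / 20)
  expect_true(all(trd$dom[trd$year >= 21] == 13))

  expect_error(nsucc_trajectory(zone, cv, full_till, conversion_schedule(10),
                                tf = 5),
               class = "cbenefit_validation_error")
})

test_that("succession engine matches the brute-force cohort oracle", {
  zone <- as.list(lookup_zone(tiny_catalog(), "temperate_oceanic_forest",
                              "cool_temperate_moist", "high_activity_clay"))
  cv <- linear_growth(zone$growth_rate_tC_ha_yr, zone$agb_max_tC_ha)
  for (tp in c(1, 7)) {
    eng <- nsucc_trajectory(zone, cv, full_till, conversion_schedule(tp), tf = 80)
    ora <- oracle_nsucc_cohort(function(a) growth_value(cv, a), tp, 80,
                               zone$root_to_shoot, zone$litter_default_tC_ha)
    expect_equal(eng$bm_above, ora$bm_above, tolerance = 1e-12)
    expect_equal(eng$bm_below, ora$bm_below, tolerance = 1e-12)
    expect_equal(eng$dom, ora$dom, tolerance = 1e-12)
  }
})

test_that("with no slow start and immediate conversion biomass is rate*(t-1/2)", {
  zone <- as.list(tiny_zones()[2, ])
  cv <- linear_growth(1.5, 70, slow_years = 0, slow_factor = 1)
  tr <- nsucc_trajectory(zone, cv, full_till, conversion_schedule(1), tf = 60)
  expect_equal(tr$bm_above,
               pmin(70, 1.5 * pmax(0:60 - 0.5, 0)), tolerance = 1e-9)
})

test_that("SRC yield, sawtooth and aggregate-constancy behave as designed", {
  cfg <- src_config(npp_pot = 5)  # defaults: 20% on-site loss, rotation 4
  expect_equal(cfg$npp_pot * (1 - cfg$l_onsite), 4)

  # immediate conversion: long-run mean standing stock is Y R / 2
  tr <- src_trajectory(cfg, full_till, soc_ref = 50,
                       conversion_schedule(1), tf = 201)
  long_run <- tr$bm_above[tr$year >= 2]  # complete rotations: years 2..201
  expect_equal(mean(long_run), 4 * 4 / 2, tolerance = 1e-6)

  # staggered cohorts: aggregate stock constant once all cohorts rotate
  for (rot in c(2, 5)) {
    cfg_r <- src_config(npp_pot = 5, rotation = rot)
    tr_r <- src_trajectory(cfg_r, full_till, 50, conversion_schedule(10),
                           tf = 60)
    vals <- tr_r$bm_above[tr_r$year >= 10 + rot]
    expect_lt(max(vals) - min(vals), 1e-9)
  }

  expect_error(src_trajectory(src_config(5, rotation = 30), full_till, 50,
                              conversion_schedule(10), tf = 20),
               class = "cbenefit_validation_error")
  expect_error(src_trajectory(cfg, full_till, 50, conversion_schedule(10),
                              tf = 5),
               class = "cbenefit_validation_error")
})

test_that("SRC engine matches the half-step cohort oracle and mass balance", {
  cfg <- src_config(npp_pot = 6, l_onsite = 0.25, rotation = 3)
  tp <- 5
  tf <- 40
  eng <- src_trajectory(cfg, full_till, 50, conversion_schedule(tp), tf = tf)
  ora <- oracle_src_cohort(6, 0.25, tp, 3, tf,
                           root_to_shoot = cfg$root_to_shoot,
                           k = cfg$litter_decay_k)
  expect_equal(eng$bm_above, ora$bm_above, tolerance = 1e-9)
  expect_equal(eng$bm_below, ora$bm_below, tolerance = 1e-9)
  expect_equal(eng$dom, ora$dom, tolerance = 1e-9)

  # discrete coppice mass balance: growth = harvested + standing
  expect_equal(ora$coppiced_cum + ora$bm_above, ora$growth_cum,
               tolerance = 1e-9)

  # production-basis harvest column integrates to Y (TF - TP/2)
  y <- 6 * 0.75
  expect_equal(sum(eng$harvest), y * (tf - tp / 2), tolerance = 1e-12)
  # and equals cumulative gross growth (standing stock is the only wedge
  # between the production basis and discrete coppicing)
  expect_equal(cumsum(eng$harvest), ora$growth_cum, tolerance = 1e-9)
})

test_that("SRC litter closed form solves the first-order litter budget", {
  # independent check of dom(t) = (I/k)(1 - exp(-k t)): explicit Euler at
  # dt = 1e-3 on a single immediately-converted cohort
  cfg <- src_config(npp_pot = 5, l_onsite = 0.2, litter_decay_k = 0.35)
  I <- 5 * 0.2; k <- 0.35
  tf <- 15
  dt <- 1e-3
  dom <- 0
  grid_dom <- numeric(tf)
  t <- 0.5  # conversion instant of the single tranche
  for (step in seq_len(round((tf - 0.5) / dt))) {
    dom <- dom + dt * (I - k * dom)
    t <- t + dt
    if (abs(t - round(t)) < dt / 2) grid_dom[round(t)] <- dom
  }
  eng <- src_trajectory(cfg, full_till, 50, conversion_schedule(1), tf = tf)
  expect_equal(eng$dom[eng$year >= 1], grid_dom, tolerance = 5e-3)
})

test_that("both options share the identical soil trajectory", {
  zone <- as.list(tiny_zones()[1, ])
  cv <- linear_growth(zone$growth_rate_tC_ha_yr, zone$agb_max_tC_ha)
  sched <- conversion_schedule(10)
  n <- nsucc_trajectory(zone, cv, full_till, sched, tf = 50)
  s <- src_trajectory(src_config(5), full_till, zone$soc_ref_tC_ha, sched,
                      tf = 50)
  expect_identical(n$soc, s$soc)
})
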