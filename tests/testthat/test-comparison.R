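fake_traj <- function(tf = 50, soc0 = 34.5) {
  tibble::tibble(
    year = 0:tf,
    bm_above = seq(0, 60, length.out = tf + 1),
    bm_below = seq(0, 15, length.out = tf + 1),
    dom = seq(0, 13, length.out = tf + 1),
    soc = soc0 + seq(0, 15.5, length.out = tf + 1))
}

test_that("cb_nsucc sums the four pool deltas", {
  tr <- fake_traj()
  expect_equal(cb_nsucc(tr, 0), 0)
  expect_equal(cb_nsucc(tr, 50), 60 + 15 + 13 + 15.5)
  # delta-based: shifting the whole SOC series changes nothing
  tr2 <- tr
  tr2$soc <- tr2$soc + 100
  expect_equal(cb_nsucc(tr2, 50), cb_nsucc(tr, 50))
  expect_error(cb_nsucc(tr, 60), class = "cbenefit_validation_error")
})

test_that("cb_be adds displacement to the pool deltas", {
  tr <- fake_traj()
  zero_disp <- tibble::tibble(year = 0:50, cb_fuel_disp = 0)
  expect_equal(cb_be(tr, zero_disp, 50), cb_nsucc(tr, 50))

  disp <- tibble::tibble(year = 0:50,
                         cb_fuel_disp = seq(0, 81, length.out = 51))
  tr_be <- tr
  tr_be$bm_above <- seq(0, 20, length.out = 51)
  tr_be$bm_below <- seq(0, 6, length.out = 51)
  tr_be$dom <- seq(0, 4, length.out = 51)
  tr_be$soc <- 34.5  # no soil change in this synthetic case
  expect_equal(cb_be(tr_be, disp, 50), 30 + 81)
})

test_that("relative benefit is the percentage ratio with parity at 100", {
  expect_equal(relative_benefit(50, 50), 100)
  expect_equal(relative_benefit(103.5, 81), 127.8, tolerance = 1e-3)
  expect_warning(out <- relative_benefit(10, 0), "undefined")
  expect_true(is.na(out))
})

test_that("the default comparison grid has full tf x DF cardinality", {
  cmp <- compare_options(tiny_profile(), tiny_catalog())
  expect_equal(nrow(cmp$table), 6 * 10)
  expect_identical(tidy(cmp), cmp$table)
  expect_equal(nrow(glance(cmp)), 1)

  # benefit identities: cb_nsucc and cb_be decompose into their pool deltas
  tab <- dplyr::left_join(cmp$table, cmp$pools, by = "tf")
  expect_equal(tab$cb_nsucc,
               tab$d_bm_above_nsucc + tab$d_bm_below_nsucc +
                 tab$d_dom_nsucc + tab$d_soc,
               tolerance = 1e-9)
  expect_equal(tab$cb_be,
               tab$d_bm_above_be + tab$d_bm_below_be + tab$d_dom_be +
                 tab$d_soc + tab$df * tab$disp_per_df,
               tolerance = 1e-9)
})

test_that("the component engine agrees with per-stratum public trajectories", {
  prof <- tiny_profile()
  cat0 <- tiny_catalog()
  params <- model_params()
  cmp <- compare_options(prof, cat0, timeframes = 60, dfs = 0.5,
                         params = params)
  sched <- conversion_schedule(params$tp)

  per_n <- per_s <- list()
  for (i in seq_len(nrow(prof))) {
    zone <- as.list(lookup_zone(cat0, prof$eco_zone[i], prof$climate_zone[i],
                                prof$soil_type[i]))
    fac <- lookup_factors(cat0, prof$tillage_class[i])
    cv <- linear_growth(zone$growth_rate_tC_ha_yr, zone$agb_max_tC_ha)
    per_n[[i]] <- as.data.frame(nsucc_trajectory(zone, cv, fac, sched, 60))
    per_s[[i]] <- as.data.frame(src_trajectory(
      src_config(prof$npp_pot[i]), fac, zone$soc_ref_tC_ha, sched, 60))
  }
  agg_n <- aggregate_region(prof, per_n)
  agg_s <- aggregate_region(prof, per_s)
  for (col in c("bm_above", "bm_below", "dom", "soc")) {
    expect_equal(cmp$trajectories$nsucc[[col]], agg_n[[col]],
                 tolerance = 1e-9, info = paste("nsucc", col))
    expect_equal(cmp$trajectories$src[[col]], agg_s[[col]],
                 tolerance = 1e-9, info = paste("src", col))
  }
  expect_equal(cmp$trajectories$src$harvest, agg_s$harvest, tolerance = 1e-9)
})

test_that("cb_be is affine in DF and the ratio declines with DF", {
  cmp <- compare_options(tiny_profile(), tiny_catalog(),
                         timeframes = c(30, 70),
                         dfs = c(0.2, 0.4, 0.6, 0.8))
  for (t in c(30, 70)) {
    sub <- cmp$table[cmp$table$tf == t, ]
    gaps <- diff(sub$cb_be)
    expect_equal(gaps[1], gaps[2], tolerance = 1e-12)
    expect_equal(gaps[2], gaps[3], tolerance = 1e-12)
    expect_true(all(diff(sub$ratio_pct) < 0))
  }
})

test_that("parity scanning handles immediate, crossing and absent parity", {
  prof <- bundled_profile()
  cat0 <- bundled_catalog()
  # high DF: bioenergy ahead from the start
  expect_equal(parity_time(prof, cat0, df = 1.0), 1L)
  # moderate DF: consistency of the returned year with the ratio
  pt <- parity_time(prof, cat0, df = 0.4)
  expect_gt(pt, 1)
  cmp <- compare_options(prof, cat0, timeframes = c(pt - 1, pt), dfs = 0.4)
  expect_lte(cmp$table$ratio_pct[cmp$table$tf == pt], 100)
  expect_gt(cmp$table$ratio_pct[cmp$table$tf == pt - 1], 100)
  # tiny DF within a short horizon: no parity
  expect_true(is.na(parity_time(prof, cat0, df = 0.05, search_horizon = 60)))
  # non-increasing in DF
  pts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(d)
    as.numeric(parity_time(prof, cat0, d, search_horizon = 150)), numeric(1))
  expect_true(all(diff(pts[!is.na(pts)]) <= 0))
})

test_that("the parity scan solves the synthetic crossing algebraically", {
  # cb_be = 2 tf against cb_nsucc = min(3 tf, 150): crossing at tf = 75
  tfs <- 1:200
  expect_identical(cbenefit:::parity_scan(pmin(3 * tfs, 150), 2 * tfs), 75L)
  # immediate superiority
  expect_identical(cbenefit:::parity_scan(rep(1, 50), rep(2, 50)), 1L)
  # still behind at the horizon
  expect_true(is.na(cbenefit:::parity_scan(pmin(3 * tfs, 150), 0.5 * tfs)))
})

test_that("the break-even DF clips at zero when succession never catches up", {
  # a desert-only stratum: negligible regrowth against a productive plantation
  z <- tiny_zones()[3, ]
  prof <- region_profile(tibble::tibble(
    eco_zone = z$eco_zone, climate_zone = z$climate_zone,
    soil_type = z$soil_type, tillage_class = "full_till",
    weight = 1, npp_pot = 6), name = "desert_only")
  expect_identical(crossover_df(prof, tiny_catalog(), tf = 50), 0)
})

test_that("the break-even DF reproduces a 100% ratio when plugged back", {
  prof <- bundled_profile()
  cat0 <- bundled_catalog()
  for (t in c(30, 50, 100)) {
    dstar <- crossover_df(prof, cat0, tf = t)
    expect_gte(dstar, 0)
    cmp <- compare_options(prof, cat0, timeframes = t, dfs = dstar)
    expect_equal(cmp$table$ratio_pct, 100, tolerance = 1e-9)
  }
})

test_that("soil carbon deltas cancel between the two options", {
  cmp <- compare_options(tiny_profile(), tiny_catalog(),
                         timeframes = c(20, 50), dfs = c(0.2, 0.8))
  expect_identical(cmp$trajectories$nsucc$soc, cmp$trajectories$src$soc)
})

test_that("replacing linear with fitted logistic growth changes the century-scale benefit only modestly", {
  prof <- bundled_profile()
  cat0 <- bundled_catalog()
  lin <- compare_options(prof, cat0, timeframes = 100, dfs = 0.5)
  logi <- compare_options(prof, cat0, timeframes = 100, dfs = 0.5,
                          params = model_params(growth_kind = "logistic"))
  rel_change <- abs(logi$table$cb_nsucc - lin$table$cb_nsucc) /
    lin$table$cb_nsucc
  expect_lt(rel_change, 0.10)
})
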