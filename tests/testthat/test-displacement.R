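mk_spec <- function(eta_be, eta_fossil, ce_bm, ce_fossil, share = 1,
                    up_bm = c(0, 0), up_fossil = c(0, 0), case = "none") {
  displacement_spec(
    route = list(eta_be = eta_be, eta_fossil = eta_fossil,
                 electricity_share = share),
    biomass_fuel = list(combustion_ef_kgCO2_GJ = ce_bm,
                        upstream_best = up_bm[1], upstream_worst = up_bm[2]),
    fossil_fuel = list(combustion_ef_kgCO2_GJ = ce_fossil,
                       upstream_best = up_fossil[1],
                       upstream_worst = up_fossil[2]),
    upstream_case = case)
}

test_that("the basic DF is the efficiency ratio times the emission ratio", {
  expect_equal(compute_df(mk_spec(0.4, 0.4, 100, 100)), 1)
  expect_equal(compute_df(mk_spec(0.36, 0.45, 112, 96.1)),
               (0.36 / 0.45) * (96.1 / 112))
  expect_equal(compute_df(mk_spec(0.36, 0.45, 112, 96.1)), 0.6864,
               tolerance = 1e-4)
  expect_equal(compute_df(mk_spec(0.40, 0.55, 112, 56.1)), 0.3643,
               tolerance = 1e-4)
  # identical CHP allocation cancels in the ratio
  expect_equal(compute_df(mk_spec(0.28, 0.40, 112, 94.6, share = 0.6)),
               compute_df(mk_spec(0.28, 0.40, 112, 94.6, share = 1)))
})

test_that("the upstream-extended DF matches its closed form and reduces exactly", {
  spec <- mk_spec(0.85, 0.90, 112, 74.1)
  expect_equal(compute_df_upstream(spec, 9, 3),
               (0.85 / 0.9) * ((74.1 + 9) / 112) - 3 / 112)
  expect_equal(compute_df_upstream(spec, 9, 3), 0.6740, tolerance = 1e-4)

  withr::with_seed(21, {
    for (i in 1:50) {
      s <- mk_spec(runif(1, 0.1, 0.95), runif(1, 0.2, 0.95),
                   runif(1, 80, 120), runif(1, 50, 100))
      expect_identical(compute_df_upstream(s, 0, 0), compute_df(s))
    }
  })
})

test_that("favorable upstream cases dominate unfavorable ones", {
  withr::with_seed(31, {
    for (i in 1:40) {
      ub <- sort(runif(2, 0, 20))
      uf <- sort(runif(2, 0, 25))
      base <- list(eta_be = runif(1, 0.2, 0.9), eta_fossil = runif(1, 0.3, 0.95),
                   ce_bm = runif(1, 90, 120), ce_fossil = runif(1, 50, 100))
      fav <- mk_spec(base$eta_be, base$eta_fossil, base$ce_bm, base$ce_fossil,
                     up_bm = ub, up_fossil = uf, case = "favorable")
      unf <- mk_spec(base$eta_be, base$eta_fossil, base$ce_bm, base$ce_fossil,
                     up_bm = ub, up_fossil = uf, case = "unfavorable")
      expect_gte(df_for_spec(fav), df_for_spec(unf))
    }
  })
})

test_that("DF is monotone in efficiencies and emission factors", {
  withr::with_seed(41, {
    for (i in 1:30) {
      eb <- runif(1, 0.1, 0.8); ef <- runif(1, 0.3, 0.9)
      cb <- runif(1, 90, 120); cf <- runif(1, 50, 100)
      d <- compute_df(mk_spec(eb, ef, cb, cf))
      expect_gt(compute_df(mk_spec(eb * 1.1, ef, cb, cf)), d)
      expect_lt(compute_df(mk_spec(eb, min(ef * 1.1, 1), cb, cf)), d)
      expect_gt(compute_df(mk_spec(eb, ef, cb, cf * 1.1)), d)
      expect_lt(compute_df(mk_spec(eb, ef, cb * 1.1, cf)), d)
    }
  })
})

test_that("closed-form cumulative displacement follows Y(1-L)(TF-TP/2)DF", {
  expect_equal(cumulative_displacement(4, 0.1, 50, 10, 0.5), 81)
  expect_equal(cumulative_displacement(4, 0.1, 50, 10, 0), 0)
  expect_equal(cumulative_displacement(4, 0.1, 10, 10, 0.5), 9)
  expect_error(cumulative_displacement(4, 0.1, 5, 10, 0.5),
               class = "cbenefit_validation_error")
})

test_that("displacement series matches the closed form for constant DF", {
  cfg <- src_config(npp_pot = 5)
  tr <- src_trajectory(cfg, list(f_lu = 1, f_mg = 1, f_i = 1), 50,
                       conversion_schedule(10), tf = 50)
  ds <- displacement_series(tr, l_supply = 0.1, df = 0.5)
  expect_equal(ds$cb_fuel_disp[ds$year == 50],
               cumulative_displacement(4, 0.1, 50, 10, 0.5),
               tolerance = 1e-9)
  expect_equal(ds$cb_fuel_disp[1], 0)
  # all-zero harvests give an all-zero series
  expect_true(all(displacement_series(rep(0, 30), 0.1, 0.8)$cb_fuel_disp == 0))
})

test_that("DF schedules interpolate linearly and clamp at the ends", {
  sched <- df_schedule(c(2020, 2050), c(0.7, 0.55))
  expect_equal(df_at(sched, 2035), 0.625)
  expect_equal(df_at(sched, c(2000, 2020, 2050, 2080)),
               c(0.7, 0.7, 0.55, 0.55))

  low <- df_schedule(c(2020, 2050, 2100), c(0.55, 0.35, 0.25))
  expect_equal(df_at(low, 2075), 0.30)

  expect_error(df_schedule(c(2020, 2020), c(0.5, 0.6)), "strictly increasing")
  expect_error(df_schedule(2020, 1.5), "\\[0, 1.2\\]")

  # a series outside the anchors errors unless clamping is requested
  h <- rep(1, 10)
  expect_error(displacement_series(h, 0.1, sched, start_year = 2045),
               class = "cbenefit_validation_error")
  ds <- displacement_series(h, 0.1, sched, start_year = 2045, clamp = TRUE)
  expect_equal(nrow(ds), 11)
})

test_that("df_table spans routes x fossil fuels x upstream cases", {
  tab <- df_table(tiny_catalog())
  expect_equal(nrow(tab), 2 * 2 * 3)
  expect_true(all(c("route", "fossil_fuel", "upstream_case", "df") %in%
                    names(tab)))
  # every no-upstream value agrees with a direct computation
  cat0 <- tiny_catalog()
  for (i in which(tab$upstream_case == "none")) {
    spec <- displacement_spec(lookup_route(cat0, tab$route[i]),
                              lookup_fuel(cat0, "wood_chips"),
                              lookup_fuel(cat0, tab$fossil_fuel[i]))
    expect_equal(tab$df[i], compute_df(spec))
  }
})
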