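test_that("catalog generation is deterministic and self-validating", {
  cfg <- generator_config(seed = 8, archetype = "mixed")
  a <- gen_catalog(cfg)
  b <- gen_catalog(cfg)
  expect_identical(a, b)  # pure function of the configuration
  expect_s3_class(a, "cb_catalog")  # construction implies validation

  # values inside the documented realistic ranges
  expect_true(all(a$zones$growth_rate_tC_ha_yr >= 0.4 - 1e-9 &
                    a$zones$growth_rate_tC_ha_yr <= 7))
  expect_true(all(a$zones$agb_max_tC_ha >= 2 & a$zones$agb_max_tC_ha <= 180))
  expect_true(all(a$zones$soc_ref_tC_ha >= 20 & a$zones$soc_ref_tC_ha <= 130))
  expect_true(all(a$fuels$combustion_ef_kgCO2_GJ >= 50 &
                    a$fuels$combustion_ef_kgCO2_GJ <= 120))
})

test_that("arid catalogs cap steppe and desert biomass at the dry-mass conventions", {
  cfg <- generator_config(seed = 4, archetype = "arid_mixed")
  cat0 <- gen_catalog(cfg)
  steppe <- cat0$zones[cat0$zones$eco_zone == "temperate_steppe", ]
  desert <- cat0$zones[cat0$zones$eco_zone == "desert", ]
  expect_equal(steppe$agb_max_tC_ha, 0.47 * 7)
  expect_equal(desert$agb_max_tC_ha, 0.47 * 2)
  # rate convention: reach the cap (plus slow-start delay) within ~22 years
  expect_equal(steppe$growth_rate_tC_ha_yr, steppe$agb_max_tC_ha / 20)

  cfg2 <- generator_config(seed = 4, archetype = "arid_mixed",
                           carbon_fraction = 0.5)
  expect_equal(gen_catalog(cfg2)$zones$agb_max_tC_ha[
    gen_catalog(cfg2)$zones$eco_zone == "desert"], 1)
})

test_that("generated regions round-trip through grid aggregation", {
  cfg <- generator_config(seed = 12, n_strata = 5)
  reg <- gen_region(cfg)
  expect_equal(sum(reg$profile$weight), 1, tolerance = 1e-12)
  back <- aggregate_grid(reg$cells)
  key <- function(p) paste(p$eco_zone, p$climate_zone, p$soil_type,
                           p$tillage_class)
  ord_a <- order(key(reg$profile))
  ord_b <- order(key(back))
  expect_equal(back$weight[ord_b], reg$profile$weight[ord_a],
               tolerance = 1e-9)
  expect_equal(back$npp_pot[ord_b], reg$profile$npp_pot[ord_a],
               tolerance = 1e-9)

  one <- gen_region(generator_config(seed = 2, n_strata = 1))
  expect_equal(one$profile$weight, 1)

  other <- gen_region(generator_config(seed = 13, n_strata = 5))
  expect_false(identical(reg$profile$weight, other$profile$weight))
})

test_that("generated artifacts feed the whole pipeline unmodified", {
  cfg <- generator_config(seed = 6, n_strata = 4, archetype = "arid_mixed")
  cat0 <- gen_catalog(cfg)
  reg <- gen_region(cfg, cat0)
  cmp <- compare_options(reg$profile, cat0, timeframes = c(20, 50),
                         dfs = c(0.3, 0.9))
  expect_equal(nrow(cmp$table), 4)
  expect_true(all(is.finite(cmp$table$ratio_pct)))
})

test_that("reference-run bundles are reproducible golden fixtures", {
  cfg <- generator_config(seed = 23, n_strata = 3)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  gen_reference_runs(cfg, dir1)
  gen_reference_runs(cfg, dir2)
  for (f in c("golden_benefits.csv", "profile.csv", "catalog/zones.csv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }

  # the golden table is what the pipeline recomputes from the stored inputs
  cat0 <- load_catalog(file.path(dir1, "catalog"))
  prof <- read_region_profile(file.path(dir1, "profile.csv"))
  golden <- readr::read_csv(file.path(dir1, "golden_benefits.csv"),
                            show_col_types = FALSE)
  cmp <- compare_options(prof, cat0, timeframes = unique(golden$tf),
                         dfs = unique(golden$df))
  expect_equal(cmp$table$cb_nsucc, golden$cb_nsucc, tolerance = 1e-9)
  expect_equal(cmp$table$cb_be, golden$cb_be, tolerance = 1e-9)

  # negative control: tampering is detected by the same comparison
  golden_bad <- golden
  golden_bad$cb_be[1] <- golden_bad$cb_be[1] * 1.01
  expect_false(isTRUE(all.equal(cmp$table$cb_be, golden_bad$cb_be,
                                tolerance = 1e-9)))
})

test_that("generated npp values are uniform over the configured range", {
  cfg0 <- generator_config(seed = 1, n_strata = 1, npp_range = c(3, 8))
  cat0 <- gen_catalog(cfg0)
  npp <- vapply(1:1000, function(s) {
    gen_region(generator_config(seed = s, n_strata = 1,
                                npp_range = c(3, 8)), cat0)$profile$npp_pot
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(npp, "punif", 3, 8))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(npp >= 3 & npp <= 8))
})
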