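#' Parameter catalogs: zone defaults, stock-change factors, fuels and routes
#'
#' A catalog bundles the four Tier 1 default-parameter tables the model needs:
#'
#' * `zones` — per (ecological zone, climate zone, soil type): net aboveground
#'   biomass growth rate of natural vegetation (tC/ha/yr), maximum aboveground
#'   biomass stock (tC/ha), root-to-shoot ratio, mature-vegetation litter stock
#'   (tC/ha) and reference soil organic carbon stock (tC/ha).
#' * `factors` — per tillage class: relative soil stock-change factors
#'   `f_lu` (land use), `f_mg` (management/tillage), `f_i` (input level),
#'   describing cropland soil carbon relative to the reference stock.
#' * `fuels` — combustion emission factors (kg CO2/GJ fuel energy) and
#'   best/worst-case upstream (supply-chain) emissions per fuel.
#' * `routes` — conversion efficiencies of a bioenergy pathway and its fossil
#'   counterpart, plus an electricity allocation share for CHP routes.
#'
#' The bundled catalog under `inst/extdata` is illustrative and
#' **non-normative**: values sit in realistic Tier 1 ranges but are not a copy
#' of any inventory table.
#'
#' @param zones,factors,fuels,routes Data frames with the documented columns
#'   (see Details).
#' @return An object of class `cb_catalog`: a named list of four validated
#'   tibbles.
#' @details Required columns:
#' * zones: `eco_zone, climate_zone, soil_type, growth_rate_tC_ha_yr,
#'   agb_max_tC_ha, root_to_shoot, litter_default_tC_ha, soc_ref_tC_ha`
#' * factors: `tillage_class, f_lu, f_mg, f_i`
#' * fuels: `name, combustion_ef_kgCO2_GJ, upstream_best, upstream_worst`
#' * routes: `name, eta_be, eta_fossil, electricity_share`
#' @examples
#' cat <- bundled_catalog()
#' lookup_zone(cat, "tropical_rainforest", "tropical_wet", "high_activity_clay")
#' @export
catalog <- function(zones, factors, fuels, routes) {
  zones <- as_tibble(zones)
  factors <- as_tibble(factors)
  fuels <- as_tibble(fuels)
  routes <- as_tibble(routes)

  check_columns(zones, c("eco_zone", "climate_zone", "soil_type",
                         "growth_rate_tC_ha_yr", "agb_max_tC_ha",
                         "root_to_shoot", "litter_default_tC_ha",
                         "soc_ref_tC_ha"), "zones")
  check_columns(factors, c("tillage_class", "f_lu", "f_mg", "f_i"), "factors")
  check_columns(fuels, c("name", "combustion_ef_kgCO2_GJ",
                         "upstream_best", "upstream_worst"), "fuels")
  check_columns(routes, c("name", "eta_be", "eta_fossil",
                          "electricity_share"), "routes")

  check_column_range(zones, "zones", "growth_rate_tC_ha_yr", lower = 0)
  check_column_range(zones, "zones", "agb_max_tC_ha", lower = 0, strict_lower = TRUE)
  check_column_range(zones, "zones", "root_to_shoot", lower = 0, upper = 2)
  check_column_range(zones, "zones", "litter_default_tC_ha", lower = 0)
  check_column_range(zones, "zones", "soc_ref_tC_ha", lower = 0, strict_lower = TRUE)
  check_no_duplicate_keys(zones, c("eco_zone", "climate_zone", "soil_type"), "zones")

  for (f in c("f_lu", "f_mg", "f_i")) {
    check_column_range(factors, "factors", f, lower = 0, strict_lower = TRUE)
  }
  prod_f <- factors$f_lu * factors$f_mg * factors$f_i
  if (any(prod_f > 1.5)) {
    bad <- which(prod_f > 1.5)[1]
    abort(sprintf(
      "Table 'factors', row %d: product f_lu*f_mg*f_i = %g exceeds 1.5.",
      bad, prod_f[bad]), class = "cbenefit_validation_error")
  }
  check_no_duplicate_keys(factors, "tillage_class", "factors")

  check_column_range(fuels, "fuels", "combustion_ef_kgCO2_GJ",
                     lower = 0, strict_lower = TRUE)
  check_column_range(fuels, "fuels", "upstream_best", lower = 0)
  check_column_range(fuels, "fuels", "upstream_worst", lower = 0)
  bad <- which(fuels$upstream_best > fuels$upstream_worst)
  if (length(bad) > 0) {
    abort(sprintf(
      "Table 'fuels', row %d, field 'upstream_best' = %g exceeds 'upstream_worst' = %g.",
      bad[1], fuels$upstream_best[bad[1]], fuels$upstream_worst[bad[1]]),
      class = "cbenefit_validation_error")
  }
  check_no_duplicate_keys(fuels, "name", "fuels")

  check_column_range(routes, "routes", "eta_be",
                     lower = 0, upper = 1, strict_lower = TRUE)
  check_column_range(routes, "routes", "eta_fossil",
                     lower = 0, upper = 1, strict_lower = TRUE)
  check_column_range(routes, "routes", "electricity_share",
                     lower = 0, upper = 1, strict_lower = TRUE)
  check_no_duplicate_keys(routes, "name", "routes")

  structure(list(zones = zones, factors = factors,
                 fuels = fuels, routes = routes),
            class = "cb_catalog")
}

#' @export
print.cb_catalog <- function(x, ...) {
  cat("<cb_catalog>\n")
  cat(sprintf("  zones:   %d rows (%d eco zones, %d climate zones, %d soil types)\n",
              nrow(x$zones), dplyr::n_distinct(x$zones$eco_zone),
              dplyr::n_distinct(x$zones$climate_zone),
              dplyr::n_distinct(x$zones$soil_type)))
  cat(sprintf("  factors: %d tillage classes\n", nrow(x$factors)))
  cat(sprintf("  fuels:   %s\n", paste(x$fuels$name, collapse = ", ")))
  cat(sprintf("  routes:  %s\n", paste(x$routes$name, collapse = ", ")))
  invisible(x)
}

catalog_files <- c(zones = "zones", factors = "factors",
                   fuels = "fuels", routes = "routes")

read_delim_auto <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    abort(sprintf("Cannot infer delimiter from extension of '%s' (use .csv or .tsv).",
                  path), class = "cbenefit_io_error")
  }
}

#' Load and save parameter catalogs
#'
#' `load_catalog()` reads the four catalog tables from a directory holding
#' `zones.csv`, `factors.csv`, `fuels.csv` and `routes.csv` (or `.tsv`;
#' delimiter is inferred from the extension) and validates every row against
#' the type invariants. `save_catalog()` writes a catalog back in the same
#' layout; numeric fields use the shortest round-trip decimal representation,
#' so save → load preserves all values exactly.
#'
#' @param path Directory containing (or to receive) the four tables.
#' @param x A `cb_catalog`.
#' @param delim Either `","` (writes `.csv`) or `"\t"` (writes `.tsv`).
#' @return `load_catalog()` a `cb_catalog`; `save_catalog()` the directory
#'   path, invisibly.
#' @export
load_catalog <- function(path) {
  if (!dir.exists(path)) {
    abort(sprintf("Catalog directory '%s' does not exist.", path),
          class = "cbenefit_io_error")
  }
  tabs <- lapply(catalog_files, function(stem) {
    hits <- file.path(path, paste0(stem, c(".csv", ".tsv")))
    hit <- hits[file.exists(hits)]
    if (length(hit) == 0) {
      abort(sprintf("Catalog table '%s' not found in '%s'.", stem, path),
            class = "cbenefit_io_error")
    }
    read_delim_auto(hit[1])
  })
  catalog(tabs$zones, tabs$factors, tabs$fuels, tabs$routes)
}

#' @rdname load_catalog
#' @export
save_catalog <- function(x, path, delim = ",") {
  stopifnot(inherits(x, "cb_catalog"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  ext <- if (delim == "\t") ".tsv" else ".csv"
  for (stem in catalog_files) {
    f <- file.path(path, paste0(stem, ext))
    if (delim == "\t") readr::write_tsv(x[[stem]], f, progress = FALSE)
    else readr::write_csv(x[[stem]], f, progress = FALSE)
  }
  invisible(path)
}

#' The bundled illustrative catalog and region profile
#'
#' A small, clearly non-normative catalog (9 ecological zones, 7 climate
#' zones, 3 soil types, 3 tillage classes, 4 fuels, 6 conversion routes) and a
#' "global-like" cropland profile spanning tropical to arid strata. They exist
#' so that examples and tests run without the global raster data a full
#' regional application would need.
#'
#' @return `bundled_catalog()` a `cb_catalog`; `bundled_profile()` a
#'   `cb_region_profile`.
#' @export
bundled_catalog <- function() {
  load_catalog(system.file("extdata", package = "cbenefit"))
}

#' @rdname bundled_catalog
#' @export
bundled_profile <- function() {
  read_region_profile(
    system.file("extdata", "profile_global.csv", package = "cbenefit"),
    name = "global_like")
}

lookup_one <- function(df, table_name, key_cols, key_vals) {
  idx <- rep(TRUE, nrow(df))
  for (i in seq_along(key_cols)) idx <- idx & df[[key_cols[i]]] == key_vals[[i]]
  hit <- which(idx)
  if (length(hit) != 1) {
    keys <- do.call(paste, c(df[key_cols], sep = " / "))
    abort(sprintf(
      "No %s entry for key '%s'. Available keys:\n  %s",
      table_name, paste(unlist(key_vals), collapse = " / "),
      paste(keys, collapse = "\n  ")),
      class = "cbenefit_lookup_error")
  }
  df[hit, ]
}

#' Look up catalog entries
#'
#' Each lookup returns the unique matching one-row tibble, or throws a lookup
#' error listing the available keys.
#'
#' @param cat A `cb_catalog`.
#' @param eco_zone,climate_zone,soil_type Zone key labels.
#' @param tillage_class,name Key labels for the factors / fuels / routes tables.
#' @return A one-row tibble.
#' @export
lookup_zone <- function(cat, eco_zone, climate_zone, soil_type) {
  stopifnot(inherits(cat, "cb_catalog"))
  lookup_one(cat$zones, "zone", c("eco_zone", "climate_zone", "soil_type"),
             list(eco_zone, climate_zone, soil_type))
}

#' @rdname lookup_zone
#' @export
lookup_factors <- function(cat, tillage_class) {
  stopifnot(inherits(cat, "cb_catalog"))
  lookup_one(cat$factors, "stock-change factor", "tillage_class",
             list(tillage_class))
}

#' @rdname lookup_zone
#' @export
lookup_fuel <- function(cat, name) {
  stopifnot(inherits(cat, "cb_catalog"))
  lookup_one(cat$fuels, "fuel", "name", list(name))
}

#' @rdname lookup_zone
#' @export
lookup_route <- function(cat, name) {
  stopifnot(inherits(cat, "cb_catalog"))
  lookup_one(cat$routes, "conversion route", "name", list(name))
}
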