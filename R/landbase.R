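#' Region profiles: weighted biophysical strata
#'
#' A region is represented as a table of strata — unique combinations of
#' (ecological zone, climate zone, soil type, tillage class) — each carrying
#' the fraction `weight` of the region's cropland area it occupies and its
#' potential net primary production `npp_pot` (tC/ha/yr), the SRC yield proxy.
#' Converted area is assumed evenly distributed over the region's cropland, so
#' regional trajectories are area-weighted means of per-stratum trajectories.
#'
#' Weights must sum to 1: a deviation below 1e-9 is accepted as-is, below 1e-6
#' the weights are renormalized with a message, anything larger is an error.
#'
#' @param strata Data frame with columns `eco_zone`, `climate_zone`,
#'   `soil_type`, `tillage_class`, `weight`, `npp_pot`.
#' @param name Region label.
#' @return A `cb_region_profile`: a tibble of strata with a `name` attribute.
#' @examples
#' region_profile(
#'   data.frame(eco_zone = "temperate_oceanic_forest",
#'              climate_zone = "cool_temperate_moist",
#'              soil_type = "high_activity_clay",
#'              tillage_class = "full_till",
#'              weight = 1, npp_pot = 4.5),
#'   name = "toy")
#' @export
region_profile <- function(strata, name = "region") {
  strata <- as_tibble(strata)
  check_columns(strata, c("eco_zone", "climate_zone", "soil_type",
                          "tillage_class", "weight", "npp_pot"), "strata")
  if (nrow(strata) < 1) {
    abort("A region profile needs at least one stratum.",
          class = "cbenefit_validation_error")
  }
  check_column_range(strata, "strata", "weight",
                     lower = 0, upper = 1, strict_lower = TRUE)
  check_column_range(strata, "strata", "npp_pot", lower = 0, strict_lower = TRUE)
  dev <- abs(sum(strata$weight) - 1)
  if (dev > 1e-9) {
    if (dev < 1e-6) {
      inform(sprintf(
        "Stratum weights sum to 1 %+.3g; renormalizing.", sum(strata$weight) - 1))
      strata$weight <- strata$weight / sum(strata$weight)
    } else {
      abort(sprintf("Stratum weights sum to %.8f, not 1.", sum(strata$weight)),
            class = "cbenefit_validation_error")
    }
  }
  structure(strata, name = name,
            class = c("cb_region_profile", class(strata)))
}

#' @export
print.cb_region_profile <- function(x, ...) {
  cat(sprintf("<cb_region_profile> '%s', %d strata\n",
              attr(x, "name"), nrow(x)))
  NextMethod()
}

profile_name <- function(profile) attr(profile, "name") %||% "region"

#' @rdname region_profile
#' @param profile A `cb_region_profile`.
#' @param cat A `cb_catalog`; every stratum's zone key and tillage class must
#'   resolve in it.
#' @export
check_profile <- function(profile, cat) {
  for (i in seq_len(nrow(profile))) {
    lookup_zone(cat, profile$eco_zone[i], profile$climate_zone[i],
                profile$soil_type[i])
    lookup_factors(cat, profile$tillage_class[i])
  }
  invisible(profile)
}

stratum_key <- function(df) {
  paste(df$eco_zone, df$climate_zone, df$soil_type, df$tillage_class, sep = "/")
}

#' Read and write region profiles
#'
#' Delimited tables with the stratum columns documented in
#' [region_profile()]; delimiter inferred from the `.csv`/`.tsv` extension.
#'
#' @param path File path.
#' @param name Region label for the loaded profile.
#' @param profile A `cb_region_profile`.
#' @export
read_region_profile <- function(path, name = "region") {
  region_profile(read_delim_auto(path), name = name)
}

#' @rdname read_region_profile
#' @export
write_region_profile <- function(profile, path) {
  out <- as_tibble(as.data.frame(profile))
  if (tolower(tools::file_ext(path)) == "tsv") {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Aggregate a grid-cell table into a region profile
#'
#' Emulates the zonal bookkeeping of a raster preprocessing step: grid cells
#' carrying cropland area are collapsed into one stratum per distinct
#' (eco_zone, climate_zone, soil_type, tillage_class). Stratum weight is its
#' share of total cropland area; stratum `npp_pot` is the cropland-area
#' weighted mean over its cells. Coordinates never enter the math, so a flat
#' cell table suffices.
#'
#' @param cells Data frame with columns `cell_id`, `eco_zone`, `climate_zone`,
#'   `soil_type`, `tillage_class`, `cropland_area` (ha), `npp_pot` (tC/ha/yr).
#' @param name Region label.
#' @return A `cb_region_profile`.
#' @examples
#' cells <- data.frame(
#'   cell_id = 1:2, eco_zone = "desert", climate_zone = "tropical_dry",
#'   soil_type = "sandy", tillage_class = "full_till",
#'   cropland_area = c(10, 30), npp_pot = c(4, 6))
#' aggregate_grid(cells)  # one stratum, npp_pot 5.5
#' @export
aggregate_grid <- function(cells, name = "region") {
  cells <- as_tibble(cells)
  check_columns(cells, c("cell_id", "eco_zone", "climate_zone", "soil_type",
                         "tillage_class", "cropland_area", "npp_pot"), "cells")
  check_column_range(cells, "cells", "cropland_area", lower = 0)
  total <- sum(cells$cropland_area)
  if (total <= 0) {
    abort("empty land base: all cells have zero cropland area.",
          class = "cbenefit_validation_error")
  }
  strata <- cells |>
    dplyr::filter(.data$cropland_area > 0) |>
    dplyr::group_by(.data$eco_zone, .data$climate_zone, .data$soil_type,
                    .data$tillage_class) |>
    dplyr::summarise(
      npp_pot = weighted.mean(.data$npp_pot, .data$cropland_area),
      weight = sum(.data$cropland_area) / total,
      .groups = "drop") |>
    dplyr::select("eco_zone", "climate_zone", "soil_type", "tillage_class",
                  "weight", "npp_pot")
  region_profile(strata, name = name)
}

#' Area-weighted regional aggregation
#'
#' Collapses per-stratum results into a regional result using the stratum
#' weights. `per_stratum` is a list, one element per profile row (in order or
#' named by the stratum key), each either a scalar, a numeric vector, or a
#' pool-trajectory tibble (all sharing length and columns; the `year` column,
#' if present, must agree and is carried through).
#'
#' @param profile A `cb_region_profile`.
#' @param per_stratum List of per-stratum values (see Details).
#' @return The weighted mean: scalar, vector, or tibble matching the inputs.
#' @export
aggregate_region <- function(profile, per_stratum) {
  stopifnot(inherits(profile, "cb_region_profile"))
  n <- nrow(profile)
  keys <- stratum_key(profile)
  if (!is.null(names(per_stratum)) && !all(names(per_stratum) == "")) {
    missing <- setdiff(keys, names(per_stratum))
    if (length(missing) > 0) {
      abort(sprintf("Missing per-stratum value(s) for: %s.",
                    paste(missing, collapse = "; ")),
            class = "cbenefit_validation_error")
    }
    per_stratum <- per_stratum[keys]
  } else if (length(per_stratum) != n) {
    abort(sprintf("`per_stratum` has %d elements but the profile has %d strata.",
                  length(per_stratum), n),
          class = "cbenefit_validation_error")
  }
  w <- profile$weight

  if (all(vapply(per_stratum, is.numeric, logical(1)))) {
    lens <- vapply(per_stratum, length, integer(1))
    if (length(unique(lens)) != 1) {
      abort("Per-stratum vectors differ in length.",
            class = "cbenefit_validation_error")
    }
    out <- Reduce(`+`, Map(function(v, wi) wi * v, per_stratum, w))
    return(out)
  }

  if (!all(vapply(per_stratum, is.data.frame, logical(1)))) {
    abort("`per_stratum` must be all numeric or all data frames.",
          class = "cbenefit_validation_error")
  }
  nrows <- vapply(per_stratum, nrow, integer(1))
  if (length(unique(nrows)) != 1) {
    abort("Per-stratum trajectories differ in length.",
          class = "cbenefit_validation_error")
  }
  cols <- names(per_stratum[[1]])
  for (tr in per_stratum[-1]) {
    if (!identical(names(tr), cols)) {
      abort("Per-stratum trajectories differ in columns.",
            class = "cbenefit_validation_error")
    }
  }
  num_cols <- setdiff(cols[vapply(per_stratum[[1]], is.numeric, logical(1))],
                      "year")
  out <- per_stratum[[1]]
  for (cl in num_cols) {
    out[[cl]] <- Reduce(`+`, Map(function(tr, wi) wi * tr[[cl]], per_stratum, w))
  }
  if ("year" %in% cols) {
    for (tr in per_stratum[-1]) {
      if (!isTRUE(all.equal(tr$year, out$year))) {
        abort("Per-stratum trajectories disagree on the year column.",
              class = "cbenefit_validation_error")
      }
    }
  }
  out
}
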