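# Internal validation helpers shared across modules.

# Default IPCC Tier 1 carbon fraction of dry matter (tC per t dry mass), used
# only to convert dry-mass biomass caps (steppe, desert) to carbon.
CARBON_FRACTION_DEFAULT <- 0.47

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "cbenefit_validation_error")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside the admissible range %s%g, %g%s.",
      name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), class = "cbenefit_validation_error")
  }
  invisible(x)
}

check_columns <- function(df, expected, table_name) {
  missing <- setdiff(expected, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "Table '%s' is missing required column(s): %s.",
      table_name, paste0("'", missing, "'", collapse = ", ")
    ), class = "cbenefit_schema_error")
  }
  invisible(df)
}

# Row/field-naming invariant check over a data frame column.
check_column_range <- function(df, table_name, column, lower = -Inf, upper = Inf,
                               strict_lower = FALSE, strict_upper = FALSE) {
  x <- df[[column]]
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("Table '%s', column '%s' must be numeric with no missing values.",
                  table_name, column),
          class = "cbenefit_validation_error")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  bad <- which(!(lo_ok & hi_ok))
  if (length(bad) > 0) {
    abort(sprintf(
      "Table '%s', row %d, field '%s' = %g violates the invariant %s%g, %g%s.",
      table_name, bad[1], column, x[bad[1]],
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), class = "cbenefit_validation_error")
  }
  invisible(df)
}

check_no_duplicate_keys <- function(df, key_cols, table_name) {
  key <- do.call(paste, c(df[key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(sprintf("Table '%s' has a duplicate key: %s.",
                  table_name, gsub("\r", " / ", dup)),
          class = "cbenefit_duplicate_key_error")
  }
  invisible(df)
}

# Stable per-purpose sub-seeds derived from one top-level seed (kept < 2^31).
derive_seed <- function(seed, label) {
  offsets <- c(catalog = 11L, region = 23L, montecarlo = 37L,
               reference = 53L, scenario = 71L)
  off <- offsets[[label]] %||% 97L
  as.integer((as.double(seed) * 7919 + off) %% 2147483647)
}
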