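# broom-style accessors for the result objects.

#' Tidy and glance methods
#'
#' `tidy()` returns the result's long table (one row per tf x DF cell, per
#' Monte Carlo summary cell, or per scenario year); `glance()` a one-row
#' summary.
#'
#' @param x A `cb_comparison`, `cb_montecarlo`, `cb_scenario` or
#'   `cb_pool_trajectory`.
#' @param ... Unused.
#' @return A tibble.
#' @name cbenefit-tidiers
NULL

#' @rdname cbenefit-tidiers
#' @method tidy cb_comparison
#' @export
tidy.cb_comparison <- function(x, ...) x$table

#' @rdname cbenefit-tidiers
#' @method glance cb_comparison
#' @export
glance.cb_comparison <- function(x, ...) {
  tibble(
    profile = profile_name(x$profile),
    n_timeframes = length(x$timeframes),
    n_dfs = length(x$dfs),
    min_ratio_pct = min(x$table$ratio_pct),
    max_ratio_pct = max(x$table$ratio_pct),
    share_nsucc_superior = mean(x$table$ratio_pct > 100))
}

#' @rdname cbenefit-tidiers
#' @method tidy cb_montecarlo
#' @export
tidy.cb_montecarlo <- function(x, ...) x$summary

#' @rdname cbenefit-tidiers
#' @method glance cb_montecarlo
#' @export
glance.cb_montecarlo <- function(x, ...) {
  tibble(n_runs = x$n_runs, seed = x$seed,
         npp_lo = x$npp_multiplier_range[1],
         npp_hi = x$npp_multiplier_range[2],
         l_onsite_lo = x$l_onsite_range[1],
         l_onsite_hi = x$l_onsite_range[2],
         median_iqr = stats::median(x$summary$q3 - x$summary$q1))
}

#' @rdname cbenefit-tidiers
#' @method tidy cb_scenario
#' @export
tidy.cb_scenario <- function(x, ...) x$table

#' @rdname cbenefit-tidiers
#' @method glance cb_scenario
#' @export
glance.cb_scenario <- function(x, ...) {
  last <- x$table[nrow(x$table), ]
  tibble(scenario = x$spec$name,
         growth_kind = x$spec$growth_kind,
         year_end = last$year,
         cb_be_end = last$cb_be,
         cb_nsucc_end = last$cb_nsucc,
         ratio_pct_end = 100 * last$cb_nsucc / last$cb_be)
}

#' @rdname cbenefit-tidiers
#' @method tidy cb_pool_trajectory
#' @export
tidy.cb_pool_trajectory <- function(x, ...) {
  tidyr::pivot_longer(
    as_tibble(as.data.frame(x))[c("year", "bm_above", "bm_below", "dom", "soc")],
    cols = -"year", names_to = "pool", values_to = "stock")
}
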