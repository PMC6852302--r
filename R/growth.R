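#' Natural-vegetation regrowth curves
#'
#' Aboveground biomass carbon accumulation of natural vegetation regrowing on
#' abandoned cropland, as a function of stand age (years since conversion).
#' Three kinds are supported:
#'
#' * `linear_capped` — the Tier 1 default: constant annual uptake at the zone
#'   growth rate, reduced to `slow_factor` (default 1/3) of that rate during
#'   the first `slow_years` (default 3) of succession, truncated at the
#'   maximum stock `cap` of the ecosystem.
#' * `logistic` — an S-shaped alternative fitted by least squares to a
#'   linear-capped source curve (see [fit_logistic()]).
#' * `chapman_richards` — `a (1 - b e^(-k t))^m`, the customary form for
#'   tropical forest regrowth, vertically shifted so growth starts at zero.
#'
#' All kinds satisfy: value(0) = 0, non-decreasing in age, bounded by the
#' cap/asymptote. Curves evaluate exactly at sub-annual ages (cohorts convert
#' at mid-year), via [growth_value()].
#'
#' @param rate Net growth rate after the slow-start phase, tC/ha/yr.
#' @param cap Maximum aboveground biomass stock, tC/ha.
#' @param slow_years Duration of the initial slow-growth phase, years.
#' @param slow_factor Fraction of `rate` realised during the slow phase.
#' @return A `cb_growth_curve` object.
#' @examples
#' cv <- linear_growth(rate = 3, cap = 90)
#' growth_value(cv, c(0, 3, 10, 40))  # 0, 3, 24, 90
#' cv$time_to_cap                     # 32 years
#' @export
linear_growth <- function(rate, cap, slow_years = 3, slow_factor = 1 / 3) {
  check_number(rate, "rate", lower = 0, strict_lower = TRUE)
  check_number(cap, "cap", lower = 0, strict_lower = TRUE)
  check_number(slow_years, "slow_years", lower = 0)
  check_number(slow_factor, "slow_factor", lower = 0, upper = 1,
               strict_lower = TRUE)
  slow_total <- rate * slow_factor * slow_years
  ttc <- if (cap <= slow_total) {
    cap / (rate * slow_factor)
  } else {
    slow_years + (cap - slow_total) / rate
  }
  new_growth_curve(
    kind = "linear_capped",
    params = list(rate = rate, cap = cap, slow_years = slow_years,
                  slow_factor = slow_factor),
    asymptote = cap,
    time_to_cap = ttc)
}

new_growth_curve <- function(kind, params, asymptote, time_to_cap = NA_real_) {
  structure(list(kind = kind, params = params, asymptote = asymptote,
                 time_to_cap = time_to_cap),
            class = "cb_growth_curve")
}

#' @export
print.cb_growth_curve <- function(x, ...) {
  cat(sprintf("<cb_growth_curve> kind: %s, asymptote: %.4g tC/ha", x$kind,
              x$asymptote))
  if (is.finite(x$time_to_cap)) cat(sprintf(", time to cap: %.4g yr", x$time_to_cap))
  cat("\n  params:", paste(names(x$params),
                           vapply(x$params, function(p) format(p, digits = 6),
                                  character(1)),
                           sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a growth curve at stand ages
#'
#' @param curve A `cb_growth_curve`.
#' @param t Stand ages in years (any non-negative numbers; negative ages
#'   evaluate to 0, which the cohort engine relies on for unconverted land).
#' @return Aboveground biomass carbon stock(s), tC/ha; same shape as `t`.
#' @export
growth_value <- function(curve, t) {
  stopifnot(inherits(curve, "cb_growth_curve"))
  tt <- pmax(t, 0)
  p <- curve$params
  v <- switch(curve$kind,
    linear_capped = pmin(
      p$cap,
      p$rate * p$slow_factor * pmin(tt, p$slow_years) +
        p$rate * pmax(0, tt - p$slow_years)),
    logistic = p$K * (stats::plogis(p$r * (tt - p$t0)) -
                        stats::plogis(-p$r * p$t0)),
    chapman_richards = {
      base <- pmax(0, 1 - p$b * exp(-p$k * tt))
      pmax(0, p$a * base^p$m - p$offset)
    },
    abort(sprintf("Unknown growth curve kind '%s'.", curve$kind)))
  if (!is.null(dim(t))) dim(v) <- dim(t)
  v
}

#' Fit a shifted logistic to a linear-capped curve
#'
#' Replaces the piecewise-linear Tier 1 curve with a smooth S-shaped
#' alternative: `f(t) = K [logis(r (t - t0)) - logis(-r t0)]`, which is exactly
#' 0 at t = 0 by the vertical shift. `K` is constrained analytically so the
#' fitted curve passes through the cap at `horizon` (hence reaches at least
#' 99% of the cap there), leaving `(r, t0)` as the two free parameters chosen
#' by least squares against the source curve sampled at integer years on
#' `[0, horizon]`.
#'
#' @param curve A `linear_capped` [growth curve][linear_growth].
#' @param horizon Fit horizon in years; must be at least the source curve's
#'   time to cap. Default 1.5 x time-to-cap.
#' @param maxit Iteration budget for the Nelder-Mead optimizer.
#' @return A `cb_growth_curve` of kind `logistic`.
#' @examples
#' lin <- linear_growth(3, 90)
#' log_cv <- fit_logistic(lin, horizon = 48)
#' growth_value(log_cv, 48) / 90  # = 1 by construction
#' @export
fit_logistic <- function(curve, horizon = NULL, maxit = 500) {
  stopifnot(inherits(curve, "cb_growth_curve"))
  if (curve$kind != "linear_capped") {
    abort("fit_logistic() expects a linear_capped source curve.",
          class = "cbenefit_validation_error")
  }
  cap <- curve$params$cap
  horizon <- horizon %||% ceiling(1.5 * curve$time_to_cap)
  if (horizon < curve$time_to_cap) {
    abort(sprintf(
      "Fit horizon (%g) must be at least the source curve's time to cap (%g).",
      horizon, curve$time_to_cap), class = "cbenefit_validation_error")
  }
  ts <- seq(0, horizon, by = 1)
  target <- growth_value(curve, ts)

  k_of <- function(r, t0) {
    denom <- stats::plogis(r * (horizon - t0)) - stats::plogis(-r * t0)
    cap / denom
  }
  sse <- function(par) {
    r <- exp(par[1]); t0 <- par[2]
    K <- k_of(r, t0)
    if (!is.finite(K) || K <= 0) return(1e12)
    f <- K * (stats::plogis(r * (ts - t0)) - stats::plogis(-r * t0))
    sum((f - target)^2)
  }
  # max slope of the logistic is K r / 4 ~ rate; centre near half time-to-cap
  start <- c(log(4 * curve$params$rate / cap), curve$time_to_cap / 2)
  opt <- optim(start, sse, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-12))
  if (opt$convergence != 0) {
    abort(sprintf(
      paste0("Logistic fit did not converge within %d iterations ",
             "(best SSE %.6g at r = %.6g, t0 = %.6g)."),
      maxit, opt$value, exp(opt$par[1]), opt$par[2]),
      class = "cbenefit_fit_error")
  }
  r <- exp(opt$par[1]); t0 <- opt$par[2]
  K <- k_of(r, t0)
  asym <- K * (1 - stats::plogis(-r * t0))
  new_growth_curve(
    kind = "logistic",
    params = list(K = K, r = r, t0 = t0, horizon = horizon, sse = opt$value),
    asymptote = asym)
}

#' Chapman-Richards growth curve
#'
#' `value(t) = a (1 - b e^(-k t))^m`, vertically shifted by its value at t = 0
#' and truncated at zero, so regrowth starts from bare cropland. The base
#' `1 - b e^(-k t)` is truncated at zero before exponentiation so b > 1 with
#' non-integer m stays defined. Parameters producing a non-monotone curve on
#' the annual grid 0..200 are rejected.
#'
#' @param a Asymptotic aboveground biomass stock, tC/ha.
#' @param b Shape parameter (dimensionless).
#' @param k Rate parameter, 1/yr.
#' @param m Shape exponent.
#' @return A `cb_growth_curve` of kind `chapman_richards`.
#' @examples
#' cr <- chapman_richards(a = 150, b = 1, k = 0.05, m = 2)
#' growth_value(cr, 200) / 150  # > 0.99
#' @export
chapman_richards <- function(a, b, k, m) {
  check_number(a, "a", lower = 0, strict_lower = TRUE)
  check_number(k, "k", lower = 0, strict_lower = TRUE)
  check_number(b, "b")
  check_number(m, "m")
  offset <- a * max(0, 1 - b)^m
  curve <- new_growth_curve(
    kind = "chapman_richards",
    params = list(a = a, b = b, k = k, m = m, offset = offset),
    asymptote = a - offset)
  vals <- growth_value(curve, 0:200)
  if (any(!is.finite(vals)) || any(diff(vals) < -1e-9)) {
    abort("Chapman-Richards parameters produce a non-monotone curve on [0, 200].",
          class = "cbenefit_validation_error")
  }
  curve
}

#' Export a curve as an annual table
#'
#' @param curve A `cb_growth_curve`.
#' @param years Integer vector of stand ages.
#' @return A tibble with columns `age` and `bm_above`.
#' @export
growth_table <- function(curve, years = 0:100) {
  tibble(age = years, bm_above = growth_value(curve, years))
}
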