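---
title: "Tier 1 carbon accounting for succession versus coppice bioenergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tier 1 carbon accounting for succession versus coppice bioenergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbenefit)
```

## The question the model answers

When cropland is taken out of production, two carbon-relevant futures
compete. Left alone, the land reverts to natural vegetation (*natural
succession*, nSucc) and acts as a long-term carbon sink. Planted with short
rotation coppice (SRC — willow, poplar, eucalyptus harvested every 2–5
years), it yields woody biomass that displaces fossil fuels. `cbenefit`
computes the cumulative per-hectare **carbon benefit** of each option over a
chosen timeframe TF and reports their ratio, using IPCC Tier 1 stock-change
accounting throughout.

For succession, the benefit is the total change in the four carbon pools —
aboveground biomass, belowground biomass, dead organic matter (litter), and
soil organic carbon:

$$CB_{nSucc} = \Delta C^{BM_{above}} + \Delta C^{BM_{below}} +
  \Delta C^{DOM} + \Delta C^{SOC}.$$

For bioenergy, the same pool terms are evaluated for the plantation and the
displaced fossil carbon is added:

$$CB_{BE} = \Delta C^{BM_{above}}_{BE} + \Delta C^{BM_{below}}_{BE} +
  \Delta C^{DOM}_{BE} + \Delta C^{SOC} + CB_{fuel\_disp},$$

with the closed form

$$CB_{fuel\_disp} = Y\,(1 - L_{supply})\,(TF - TP/2)\,DF,$$

where $Y$ is the plant-gate yield in tC/ha/yr, $L_{supply}$ the supply-chain
loss, TP the transition period of gradual land conversion, and DF the
**displacement factor** — fossil carbon avoided per unit of biomass carbon
burned at equal final energy:

$$DF = \frac{\eta_{BE}}{\eta_{fossil}} \cdot \frac{CE_{fossil}}{CE_{BM}},
\qquad
DF_{incl.UE} = \frac{\eta_{BE}}{\eta_{fossil}} \cdot
  \frac{CE_{fossil}+UE_{fossil}}{CE_{BM}} - \frac{UE_{BM}}{CE_{BM}}.$$

The ratio $100 \cdot CB_{nSucc}/CB_{BE}$ is the headline quantity: above
100% succession is the better use of the hectare.

## The cohort engine

Conversion is gradual: over a transition period of TP years (default 10,
with 20 as the sensitivity alternative) one TP-th of the area converts each
year, at the **mid-year instant** $\tau_i = i + 0.5$. Each tranche is an age
cohort with its own stocks:

* **Succession biomass** follows the growth curve at the cohort's stand age;
  belowground biomass is the zone's root-to-shoot ratio times aboveground.
* **SRC biomass** grows at $Y = NPP_{pot}(1 - L_{onsite})$ per year since the
  last coppice and is cut to zero at every rotation boundary — the classic
  per-cohort sawtooth. Staggered cohorts make the aggregate stock constant
  once every cohort has completed a rotation.
* **Litter** ramps linearly from zero to the zone default over 20 years
  (succession), or accumulates as a first-order pool
  $(I/k)(1-e^{-k\,age})$ fed by on-site losses $I = NPP_{pot} L_{onsite}$
  (SRC, default $k = 0.35$/yr with steady state $I/k$).
* **Soil** moves linearly from the cropland stock
  $SOC_{ref} \cdot F_{LU} F_{MG} F_I$ to the reference stock over 20 years
  and is *identical across options* (all stock-change factors are 1 for both
  forest and plantation under Tier 1), so it cancels in the comparison. We
  apply the soil ramp region-wide from year 0 rather than per tranche; since
  the term cancels, the convention has no effect on any reported ratio.

The mid-year convention is not cosmetic: it makes the closed form
$Y(1-L)(TF-TP/2)DF$ an *exact identity* of the time-resolved engine (the
average cohort loses exactly TP/2 producing years), which the acceptance
suite verifies to 1e-9 over TP ∈ {1, 10, 20}, TF ∈ {20…100} and DF ∈
{0.1…1}.

### Harvest bookkeeping

Two readings of "harvest" coexist in coppice accounting. The *discrete*
reading books carbon at coppice events ($Y \cdot R$ every R years per
cohort); the *production* reading books the yield flux continuously (after
the transition the aggregate stock is constant, so annual production equals
annual harvest). Only the production basis integrates exactly to
$Y(TF - TP/2)$; the discrete basis differs by the standing remainder
$Y \cdot (age \bmod R)$ per cohort. The `harvest` column of
`src_trajectory()` therefore reports the production flux, and the discrete
mass balance (cumulative growth = coppiced carbon + standing stock) is
verified separately against a brute-force cohort simulation in the tests.
Note that the pool terms of $CB_{BE}$ retain the standing stock while the
displacement term integrates all production; the two equations are applied
literally, so the standing stock contributes through both routes. This
overlap is inherent to the accounting convention, is small (at most
$1.3\,Y R/2$ tC/ha), and is constant after the transition.

## Growth curves

Three curve kinds describe natural regrowth, all anchored at zero biomass
(abandoned cropland), non-decreasing and bounded:

* **linear_capped** (default): constant annual uptake at the zone's Tier 1
  rate, reduced to one third during the first three years (young stands
  accumulate slowly), truncated at the ecosystem's maximum stock. The slow
  start is applied per cohort (age-based), and both `slow_years` and
  `slow_factor` are parameters. Steppe and desert vegetation uses the same
  form with caps of 0.47 × 7 and 0.47 × 2 tC/ha (the Tier 1 carbon fraction
  times the conventional dry-mass maxima) and rate cap/20 by default.
* **logistic**: $f(t) = K[\mathrm{logis}(r(t-t_0)) - \mathrm{logis}(-r t_0)]$,
  fitted to the linear curve by least squares. The vertical shift (rather
  than constraining $t_0$) keeps $f(0)=0$ while preserving two free
  parameters; $K$ is eliminated analytically by requiring the curve to pass
  through the cap at the fit horizon (default 1.5 × time-to-cap), which
  guarantees at least 99% of the cap there. The Nelder–Mead fit is checked
  against an independent grid search in the tests.
* **chapman_richards**: $a(1 - b e^{-kt})^m$, shifted by its value at 0 and
  truncated below at zero; the customary tropical-forest form. Parameters
  are user-supplied per ecological zone (`cr_params`) — no published
  parameter table is bundled.

Replacing linear with fitted logistic growth changes the bundled profile's
100-year succession benefit by well under 10% (regression-tested), so the
default linear curves are not the driver of the headline results.

## Regional aggregation and the synthetic land base

A region is a table of biophysical strata — (ecological zone, climate zone,
soil type, tillage class) — with cropland-area weights summing to 1 and a
potential-NPP value per stratum. Converted area is assumed evenly spread
over the region's cropland, so regional curves are weight-averaged
per-stratum curves. `aggregate_grid()` collapses a flat grid-cell table into
such strata; no coordinates or projections are involved because the math is
purely zonal.

The real study behind this model used global 5-arc-minute rasters of
climate, soils, ecological zones and cropland shares. Those data are out of
scope here; instead:

* a small bundled catalog and a "global-like" nine-stratum profile (tropical
  to arid) ship under `inst/extdata`. Their values sit in realistic Tier 1
  ranges but are **non-normative** — chosen once so the qualitative DF
  ordering (succession superior at DF ≤ 0.2 everywhere; bioenergy superior
  at DF ≥ 0.6 from 30 years) holds, which is a property of plausible
  land bases, not a reproduction of any published number;
* `gen_catalog()`/`gen_region()` draw seeded synthetic catalogs and regions
  (weights from a symmetric Dirichlet, NPP uniform on 3–8 tC/ha/yr — a range
  spanning temperate cropland to productive tropical sites). They emulate
  the *product* of raster preprocessing, not spatial autocorrelation or real
  cropland geography, so a green test establishes internal consistency of
  the accounting, never agreement with the real global land base.

## Sensitivity machinery

`run_monte_carlo()` redraws, per run, one region-wide NPP multiplier
(uniform ±20%) and one on-site loss fraction (uniform 10–30%), keeping
supply-chain losses at 10%; under these defaults the highest achievable
yield is (1.2·0.9)/(0.8·0.7) ≈ 1.93 times the lowest. Box statistics use
quantile type 7 (inclusive linear interpolation) for cross-implementation
reproducibility. Draws are taken once up front from a seeded stream, so a
fixed seed gives bitwise-identical output; the deterministic comparison and
the Monte Carlo runs share one internal component engine, so degenerate
ranges reproduce the deterministic ratio exactly rather than approximately.

`run_scenario()` evaluates time-varying DF schedules (anchored at calendar
years, linearly interpolated, clamped outside the anchors) over 2020–2100.
The built-in HIGH schedule (0.7 → 0.55 in 2050 → 0.4 in 2100) describes
coal/oil displacement giving way to gas and efficient second-generation
biofuels; LOW (0.55 → 0.35 → 0.25) a faster decarbonization in which
biomass ends up in less efficient biofuel routes. Only the three printed
anchors are used; behaviour between 2020 and 2030 is linear by construction.
Elsewhere, `displacement_series()` refuses a schedule that does not cover
the series span unless clamping is requested explicitly — scenarios clamp,
ad-hoc series default to the stricter contract.

## Numerical choices and edge cases

* Annual reporting at integer years; sub-annual structure (mid-year
  conversion, coppice instants) is handled exactly in closed form, never by
  interpolating annual samples.
* Parity time is a sustained criterion: the smallest year from which the
  bioenergy benefit stays at or above succession's through the horizon.
  SRC outgrows young natural vegetation, so its benefit curve typically
  starts above, dips below at low DF, and recrosses; the recrossing is the
  policy-relevant parity point, and a plain first-crossing scan would return
  year 1 for every DF. Ties break to the earliest year; the scan is annual
  (no root finding) to match the model's resolution.
* The break-even DF inverts the affine DF-dependence of $CB_{BE}$ in closed
  form and is clipped at zero; plugging it back reproduces a 100% ratio to
  1e-9.
* In the upstream-extended DF we read the biomass upstream term as incurred
  per unit of biomass energy *outside* the efficiency ratio (the printed
  grouping is typographically ambiguous); at zero upstream emissions the
  extended form reduces to the basic DF exactly, which the suite asserts
  over a 1000-point random grid.
* Stratum weights may drift from 1 by up to 1e-6 (renormalized, with a
  message) to tolerate rounded input files; larger deviations are errors.
* Relative benefit at $CB_{BE} = 0$ is reported as `NA` with a warning, not
  as infinity.
* CHP routes carry a single electricity allocation share applied to both
  systems alike; it cancels in the DF ratio and exists so asymmetric
  allocations can be expressed by editing one factor.

## Known limitations

Dead wood (disregarded under Tier 1), albedo differences, disturbance
(fire, storm, later reconversion), nutrient or water limits on yields,
yield decline over successive rotations, market-mediated displacement below
1:1, perennial grasses, and BECCS are all outside the model, as are
economics and policy instruments. Absolute per-hectare numbers from the
bundled profile are illustrative only; any real application must supply its
own catalog and land base.
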