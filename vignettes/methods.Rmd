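---
title: "Methods: from wearable PM traces to exposure determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wearable PM traces to exposure determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wearpm)
```

This vignette documents the models, the tunable parameters and the design
decisions behind `wearpm`. It states no empirical result that the test
suite or `scripts/acceptance.R` do not themselves compute.

## 1. The measurement model

Each child carries a backpack monitor logging PM2.5, PM10 (µg/m³) and GPS
position at 1-s cadence from Monday ~10:00 to Friday ~10:00 (96 h). All
study sites are effectively DST-free, so timestamps are local clock time
without offsets and time arithmetic is linear.

**Minute aggregation.** Samples are averaged over half-open calendar
minutes `[t, t + 60 s)`. A minute's PM mean is *valid* when at least 30 of
its ≤ 60 samples carry finite PM — a 50% rule balancing dropout tolerance
against within-minute selection bias; the source campaign did not publish
its threshold, so it is a package decision exposed as
`config$qc$minute_valid_min`. GPS is valid with ≥ 1 finite fix; the minute
position is the arithmetic mean of fixes, adequate at city scale (no
great-circle averaging). PM readings ≥ 10,000 µg/m³ (or negative) are
physically implausible and blanked rather than truncated. Missing values
are empty CSV fields, never sentinel numbers.

## 2. Validity screening

Children are analysed only with **more than 24 h of continuous valid
data**. "Continuous" is not defined by the campaign's public description;
we tolerate internal invalid stretches of ≤ 5 minutes inside a run (sensor
hiccups) and count only valid minutes toward the 1440-minute threshold,
with strict inequality. A config switch (`qc$count_clock_time`) counts
elapsed clock minutes instead, since it is unknowable which accounting the
original study used; the default is the stricter valid-minute count.

Children with **more than 12 h of cumulative missing GPS** are excluded
*only* from proportion-of-time and proportion-of-exposure outputs (their
labelled means survive) — mirroring the published analysis, which removed
such children only from the proportions figure. The exclusion ledger
enumerates exactly the published exclusion reasons (no questionnaire,
withdrawal, backpack never at school, monitor failure, insufficient
continuous data), with screening precedence in that order.

## 3. Microenvironment tagging

The campaign's actual GPS-tagging algorithm lives in an unavailable
appendix; the geofence scheme here is a declared stand-in, not a fidelity
claim. Anchors:

* **home** = centroid of overnight fixes (22:00–05:00), **school** =
  centroid of school-hour fixes (10:00–14:00 on school days), each taken
  over the densest 50 m grid cell *and its 8 neighbours*. The 3×3
  neighbourhood removes the half-cell quantisation bias of a single-cell
  centroid (up to ~35 m for 30 m GPS noise) while still rejecting
  excursions; with 30 m jitter and n = 420 fixes the inferred anchor lands
  within a few metres of the generating cluster centroid (tested).
* Geofence radii default to 100 m (urban GPS error plus school-ground
  extent). Anchors closer than the larger radius raise an anchor-conflict
  error; overlapping fences with separated anchors are resolved by nearest
  anchor.

Labelling: fence minutes → `home`/`school`; GPS-valid minutes strictly
between a home-fence exit and the next school-fence entry (or reverse) →
`commute` when the fence-to-fence gap is ≤ 120 min, else `other` (this
window stops all-day truancy being scored as commuting); remaining
GPS-valid minutes → `other`; GPS-invalid minutes inherit the previous
label for ≤ 60 min (`carry_forward`), then `unknown`. Distances use the
equirectangular approximation (< 0.1% error at city scale), avoiding a
geodesy dependency for 100 m decisions.

## 4. Exposure metrics

* **Daily means**: arithmetic means of valid minutes per local calendar
  day, retained at ≥ 1080 valid minutes (75%). With a Monday ~10:00 start
  this retains the full Tuesday–Thursday days; the partial Monday (840
  possible minutes) and Friday tail can never qualify. This is a known,
  deliberate divergence: the published analysis evidently used a day
  accounting under which Mondays qualified (its model has a Monday level),
  but it did not state one, and calendar days keep day-of-week an honest
  covariate. The synthetic daily-level generator plants Monday–Thursday
  labels directly so the covariate is exercised.
* **Microenvironment summaries**: per child × label means/medians over
  valid minutes; the PM2.5:PM10 statistic is the *mean of per-minute
  ratios* with a PM10 ≥ 1 µg/m³ guard (per-child mean ratios are what the
  published figure plots); the ratio of means is emitted alongside as a
  sensitivity column. Proportions are computed over labelled
  (non-`unknown`) minutes and sum to 1 by construction.
* **Diurnal profiles**: child-hour means pooled per city, then per clock
  hour the median, mean, quartiles and 5th/95th percentiles (type-7
  linear-interpolation quantiles).
* **Guideline compliance**: strict `daily mean < 15` (PM2.5) and `< 45`
  (PM10) µg/m³ counts; thresholds live in config.

## 5. Statistical inference

**Rank tests.** Kruskal–Wallis H uses midranks and the tie correction
`1 − Σ(t³−t)/(N³−N)`; all-identical data defines H = 0, p = 1. Dunn's
pairwise z uses the pooled-variance form with the Σ(t³−t) tie term, and
Holm's step-down adjustment is applied within the pair family of a single
test, never pooled across outcomes.

**The determinants model.**
`log(daily PM2.5)_ijk = α + u_i + u_ij + Σ β_n x_ijk + ε_ijk` with child
nested in city random intercepts, fitted by REML (lme4), then the optimum
polished against an in-package restricted-likelihood evaluator built on
the Woodbury identity. That evaluator also supplies **Satterthwaite
denominator degrees of freedom**: df_j = 2 v_jj² / (gᵀ A g), where v_jj is
the coefficient's variance, g its finite-difference gradient in the
variance parameters, and A = 2H⁻¹ from the finite-difference Hessian of
the −2 restricted log-likelihood. The published analysis used the
lmerTest defaults, which is this approximation; when the Hessian is not
usable the package falls back to the normal approximation and flags
`ddf_method = "normal"` in the output. Wald CIs are used (the publication
does not say Wald vs profile); AIC is always reported from an ML refit so
fixed-effect sets are comparable (REML AICs are not); "Not reported" is a
modelled factor level, never imputed. AIC screening adds each candidate
singly to the base model and drops it only if AIC increases *and* p ≥
0.05 — single-term screening was chosen because the published screening
order is unstated.

**Numerical edges.** Constant outcomes short-circuit to a degenerate fit
(α = log constant, zero variances). Rank-deficient designs error with the
aliased column names. Variance components at the boundary are pinned to
zero and excluded from the Satterthwaite parameter set.

## 6. The synthetic world

The generator emulates the campaign's *structure*, with defaults equal to
its published summary statistics:

* City daily-exposure geometric means/GSDs: Blantyre 45.7/1.6, Durban
  18.8/2.2, Harare 21.4/1.6, Kumasi 18.3/1.6, Lagos 24.1/1.5,
  Moshi 29.1/1.5; child counts 24/47/43/61/61/61; meteorology means/SDs
  per city from the same table.
* The within-city log-variance `log(GSD)²` is split 60/40 between a
  child-level random intercept and day-level noise. The split is a package
  choice (the publication reports no variance components); 60% child share
  makes between-child spread dominate, which matches the published
  description of drastic between-child variation.
* Planted determinant effects default to the published point estimates
  converted to factors (smoking 1.230, coal/wood 1.271, kerosene lamp
  1.302, paved school ground 0.628, no commute 0.817, temperature 1.056
  per °C, wind 0.916 per m·s⁻¹). They are calibration conveniences for
  recovery testing, not claims of truth.
* Minute noise is lognormal AR(1) with ρ = 0.9 and stationary log-SD 0.35,
  giving persistent micro-events and a realistic effective sample size for
  daily means; the schedule is school 08:00–14:00, commutes 07:00–08:00
  and 14:00–15:00, home otherwise; biomass/open-fire homes get a 3×
  cooking multiplier at 05:00–06:00 and 18:00–19:00, reproducing the
  published twin diurnal peaks.
* Microenvironment exposure multipliers (home 0.95, school 1.35, commute
  1.15) are **not** part of the published record; they exist because
  microenvironment contrasts need a truth to recover. They are normalised
  so the schedule-weighted mean factor is 1, preserving the city GM for
  daily means. PM10 is derived per minute as PM2.5 / ratio(label), with
  lower school ratios in the four dusty-school cities (coarse dust).
* Commute GPS paths run fence edge to fence edge, so in the noiseless
  limit the geofence tagger reproduces the schedule exactly — this makes
  "accuracy = 1.0 with zero noise" a meaningful identity test rather than
  an approximation.
* GPS dropout alternates exponential up/down segments (mean down-time 10
  min) hitting the configured dropout rate; designated children receive a
  planted 14 h gap to exercise the > 12 h rule.

**What a green test does not establish:** the generator has no sensor
physics (humidity interference, size-bin cut points), no street networks,
no weekend behaviour, no seasonal trend, and its determinants are drawn
independently per child (no socioeconomic confounding structure). Recovery
results validate the *pipeline arithmetic and inference machinery*, not
the field realism of the defaults.

## 7. Seeds and determinism

Every generator function is a pure function of its seed; traces, cohorts
and output CSVs are byte-identical across reruns. Derived seeds stay below
2³¹. Two published-seed examples from the build specification
(single-seed ±6 pp effect recovery; a noise covariate dropped at one
seed) are realisations of the *spec author's* generator and do not
transfer to an independent implementation; the package tests the
corresponding claims distributionally (95% CI coverage ≥ 88% and null
rejection within [0.02, 0.09] over 200 cohorts) and via 2-SE single-run
bounds.

## 8. Known limitations

* The geofence tagger is a stand-in for the campaign's unpublished
  algorithm; minute labels near fence boundaries are the main error
  source (~0.3–1% of minutes at default noise).
* Satterthwaite df are finite-difference approximations; in tiny designs
  (< 3 cities) they can be unstable, triggering the flagged normal
  fallback.
* Calendar-day daily means cannot produce Monday observations from real
  Monday-start traces (see §4).
* The PM2.5:PM10 ratio analysis assumes the two channels share a minute
  clock; no cross-channel drift correction is attempted.
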