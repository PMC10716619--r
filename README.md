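# wearpm

Analysis of **personal PM2.5 / PM10 exposure** measured with GPS-enabled
wearable monitors carried by school children. The package targets the
standard design of urban personal-exposure campaigns in which each child
carries a backpack sensor logging particulate matter and position at 1-s
cadence from Monday mid-morning to Friday mid-morning, answers a
questionnaire on household exposure determinants (cooker type, lighting,
smoking, commute mode, school-ground surface, ...), and fills in a daily
diary. It is written for exposure scientists and epidemiologists who need a
tested, reproducible path from raw sensor traces to determinant estimates.

## What it does

1. **Trace ingestion & QC** (`read_trace`, `aggregate_minutes`,
   `validity_report`, `build_exclusion_ledger`): second-level samples are
   aggregated to minutes (a minute's PM is valid when ≥ 30 of its ≤ 60
   samples carry finite PM); children are retained only with **more than
   24 h of continuous valid data** (internal invalid gaps ≤ 5 min
   tolerated); children with **more than 12 h of missing GPS** are flagged
   out of proportion-of-exposure analyses only.
2. **Microenvironment tagging** (`infer_anchors`, `tag_minutes`): home and
   school anchors are inferred as densest-cell centroids of overnight
   (22:00–05:00) and school-hour (10:00–14:00) fixes on a 50 m grid;
   minutes are labelled `home` / `school` inside 100 m geofences, `commute`
   on fence-to-fence transitions ≤ 120 min, `other` elsewhere, with ≤ 60
   min carry-forward over GPS dropouts, then `unknown`.
3. **Exposure metrics** (`daily_means`, `microenv_summaries`,
   `diurnal_profiles`, `guideline_compliance`): daily means (≥ 75%
   coverage), per-microenvironment means and PM2.5:PM10 **coarse-fraction
   ratios** (low ratios indicate resuspended dust), time / exposure
   proportions, city-level diurnal profiles, and WHO 24-h guideline
   compliance (daily mean < 15 µg/m³ for PM2.5, < 45 µg/m³ for PM10).
4. **Inference** (`kruskal_wallis`, `dunn_posthoc`, `fit_lmm`, `vif`,
   `aic_screen`): tie-corrected Kruskal–Wallis H with Dunn post-hocs and
   Holm adjustment, and the nested random-intercept log-linear model

   log(PM2.5)_ijk = α + u_i(city) + u_ij(child) + Σ β_n x_ijk + ε_ijk

   fitted by REML, with Satterthwaite denominator degrees of freedom,
   ML-refit AIC screening, VIF diagnostics, and effects reported as
   percent change, (exp(β) − 1) × 100, with 95% CIs.
5. **Synthetic cohort generator** (`generate_cohort`, `generate_traces`,
   `generate_daily_exposures`, `score_against_truth`): seeded cohorts with
   city-level lognormal exposure heterogeneity (published geometric
   means/GSDs as defaults), schedules, GPS jitter/dropout, planted
   multiplicative determinant effects and known minute-level ground truth,
   so the whole pipeline is testable without any field data.

## Worked example

Two-city synthetic cohort (6 children each), full pipeline from 1-s traces:

```r
library(wearpm)
cfg <- default_config()
cfg$generator$cities <- cfg$generator$cities[c(1, 4), ]   # Blantyre, Kumasi
cfg$generator$cities$n_children <- c(6L, 6L)
res <- run_pipeline(cfg, out_dir = "demo_out", seed = 1)

res$scorecard$accuracy        # minute-level tagging accuracy vs truth
res$compliance                # WHO guideline day counts
dd <- merge(res$daily, res$cohort[, c("child_id", "city_id")])
aggregate(pm25_daily_mean ~ city_id, dd, median)
kruskal_wallis(split(dd$pm25_daily_mean, dd$city_id))
```

Output of this exact script:

```
tagging accuracy: 0.997
days below WHO PM2.5 guideline: 8 of 36 (22.2%)
   city_id pm25_daily_mean
1 Blantyre            43.1
2   Kumasi            20.8
Kruskal-Wallis H = 11.25 (df = 1), p = 0.0008
```

The geofence tagger recovers 99.7% of the generator's true minute labels
under 30 m GPS jitter and 10% dropout; daily medians reflect the configured
city geometric means (Blantyre 45.7, Kumasi 18.3 µg/m³); the rank test
confirms the between-city exposure difference. `run_pipeline` writes
`daily_exposure.csv`, `microenv_summary.csv`, `diurnal_profile.csv`,
`compliance.csv`, `exclusion_ledger.csv`, `characteristics_table.csv`,
`determinants_model.csv` (when identifiable) and `manifest.json` to
`out_dir`.

## Command line

```sh
Rscript -e 'wearpm::wearpm_cli()' generate --config cfg.json --seed 1 --out data/
Rscript -e 'wearpm::wearpm_cli()' run --config cfg.json --seed 1 --in data/ --out out/
```
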