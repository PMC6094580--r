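# actisig

Multivariate physical-activity intensity signatures for metabolic health.

## What this is for

Pediatric accelerometer studies usually reduce activity to a few cut-point
classes (sedentary / light / moderate / vigorous) before relating it to
health. `actisig` instead treats the **whole intensity spectrum** — minutes
per day in 16 narrow counts-per-minute bins, 0–99 up to ≥ 8000 cpm — as one
multivariate exposure, and asks *which intensities* carry the association
with metabolic health. The audience is researchers in physical-activity
epidemiology and chemometrics-style multivariate pattern analysis.

The core method, for outcome vector *y* (a metabolic risk factor, or a
composite risk score) and bin matrix *X* (n subjects × 16 bins, autoscaled):

* **PLS1 regression** (NIPALS): components maximize covariance between bin
  combinations and *y*; handles the near-complete collinearity of adjacent
  bins (r ≈ 0.91). The number of components A\* is chosen by **Monte-Carlo
  resampling**: 100 random 50/50 splits, A\* = argmin of the median
  validation RMSEP (ties → fewer components).
* **Target projection**: the fitted model is rotated onto the single
  direction of its regression vector, w_tp = b/‖b‖, t_tp = X·w_tp, so all
  predictive variance sits in one component (fitted values are preserved
  exactly).
* **Selectivity ratios**: per bin, SR_i = sign(p_tp,i) · v_expl,i / v_res,i
  — explained over residual variance on the predictive component, signed by
  the loading. Large |SR| = important intensity; negative = associated with
  better health. Confidence intervals come from the same 100 resampling
  halves (percentile or symmetric jackknife-style).
* **Composite score**: six age/sex-residualized risk factors (systolic BP,
  triglycerides, TC:HDL, HOMA-IR, waist:height, reversed aerobic-fitness
  distance) are z-scored, averaged, and rescaled to SD 1; higher = worse.

Upstream, the package turns raw epoch streams (10-s epochs) into spectra
with the standard wear rules — hours 06:00–23:59, non-wear = ≥ 60 min of
consecutive zeros, valid = ≥ 8 h/day on ≥ 4 days — and downstream it exports
tables, SR-plot data, and cut-point sensitivity analyses. A calibrated
synthetic-cohort generator (`simulate_cohort()`, `simulate_epochs()`)
provides data with known ground truth for every test.

## Worked example

```r
library(actisig)

cohort <- simulate_cohort(cohort_config(seed = 1))    # n = 841, effect on bins 13-14
outc   <- build_outcomes(cohort$panel)                # residualize + composite
round(c(mean(outc$composite), sd(outc$composite)), 3)
#> [1] 0 1

sig <- fit_signature(cohort$features, outc$composite, seed = 1)
print(sig)
#> <signature_profile> A* = 2, training R2 = 0.125
#>     variable     sr   lower   upper significant
#> 1       0-99  0.262   0.107  0.4568        TRUE
#> 2    100-249 -0.197  -0.405 -0.0610        TRUE
#> ...
#> 12 4500-4999 -6.257  -7.544 -3.9888        TRUE
#> 13 5000-5999 -8.397 -10.088 -5.4381        TRUE
#> 14 6000-6999 -8.267 -10.709 -4.9150        TRUE
#> 15 7000-7999 -5.001  -6.568 -3.3082        TRUE
#> 16    >=8000 -2.893  -3.733 -2.0002        TRUE
```

Reading this: the resampling rule kept 2 PLS components (training
R² = 0.125, close to the generator's true 0.133). The largest negative SRs
sit at 5000–6999 cpm — exactly the bins where this synthetic cohort's
ground-truth effect was placed — meaning time at those intensities
accompanies better metabolic health; the positive sedentary-bin SR reflects
its negative correlation with the active bins. Univariately the same cohort
gives r = 0.14 for the sedentary bin and −0.34 / −0.35 for bins 13–14
against the composite (significance boundary at n = 841: |r| ≥ 0.0676).

The full pipeline (features → outcomes → univariate table → signatures →
CSV/JSON artifacts) runs from one config:

```r
res <- run_pipeline(pipeline_config(features = cohort$features,
                                    panel = cohort$panel,
                                    out_dir = "out", seed = 1,
                                    per_outcome = TRUE))
```

or from the command line via `Rscript inst/cli/actisig.R run-all
--features features.csv --panel panel.csv --out out --seed 1`.

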