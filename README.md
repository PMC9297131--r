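# searchcycles

Diurnal and day-of-week rhythm analysis for hourly search-interest time
series.

## What problem this solves

Hourly relative search volume (RSV) from sources like Google Trends carries
a strong 24-hour cycle whose timing and strength are clinically informative
for many health terms: when in the day people search for a symptom, how
pronounced that daily cycle is, and whether weekday and weekend behaviour
differ. Extracting those quantities is complicated by a slowly drifting
baseline, epidemics and media-driven surges that bias any naive periodic
fit, and Trends' per-request 0–100 renormalization noise.

`searchcycles` is for epidemiologists and infodemiology researchers who want
those rhythm summaries, with honest uncertainty, from a reproducible
pipeline.

## The model

For hourly RSV `y(x)` with local clock time `t` and elapsed hours `x`, the
package fits the Serfling-type harmonic regression

```
y(x) = b0 + cubic trend in x/24 (orthogonal polynomials)
     + sum_{daytype in {weekday, weekend}} 1{daytype}
           sum_{n=1..4} [ a_n sin(n w t) + b_n cos(n w t) ],   w = 2*pi/24
     + weekend level
     + sum_{selected (k,m)} eta_{k,m} 1{ k*m <= x <= k*(m+1)-1 }   + error
```

The last block is an interval-indicator basis (window widths
k = 8, 16, 32, 64, 128, 168 hours tiling the year) that absorbs epidemics
and other localized outliers; a cross-validated LASSO (penalty on the
indicators only, one-standard-error rule) selects a small subset, after
which all coefficients are re-estimated by OLS.

From the fitted weekday and weekend diurnal curves the package computes the
circular median peak time, the amplitude-to-mean ratio
(peak-to-trough / mean), and a weekday–weekend cyclic-strength contrast,
with percentile confidence intervals and diurnality P values from a
residual-based circular moving-block bootstrap (fixed 20-hour blocks).
A synthetic-data generator with known ground truth, polar 24-hour plots and
an end-to-end `run_analysis()` driver complete the pipeline. See the
vignette `vignettes/diurnal-rhythms.Rmd` for the full methods account.

## Worked example

Simulate one year of Trends-like data — baseline 50, weekday harmonics of
amplitude 10 and 3 peaking at 05:00 and 02:00, a weekend harmonic of
amplitude 6 peaking at 07:00, noise sd 5, and a +60 epidemic surge lasting
8 hours — then run the fit and bootstrap:

```r
library(searchcycles)

spec <- synthetic_spec(
  n_hours = 8760, baseline = 50, trend_coeffs = c(0.05, -3e-4, 4e-7),
  harmonics = list(weekday = harmonic_set(c(1, 2), c(10, 3), peak_hour = c(5, 2)),
                   weekend = harmonic_set(1, 6, peak_hour = 7)),
  noise_sd = 5, outliers = list(c(800, 8, 60)), seed = 42)
sim    <- simulate_series(spec)
design <- build_design(sim$series)
model  <- fit_series(sim$series$rsv, design, seed = 42)
model$nuisance_coeffs
#>       col width   m     coef
#> 1 k8_m100     8 100 59.48542
sm <- bootstrap_summaries(model, bootstrap_config(n_reps = 500, seed = 42),
                          term = "demo term")
```

The LASSO found exactly the indicator covering the injected surge (hours
800–807, estimated height 59.5 vs the true +60). The summary row, formatted:

```
weekday median 04:57 (04:53, 05:01)  amr 0.442 (0.432, 0.454)
weekend median 07:12 (07:02, 07:24)  amr 0.233 (0.221, 0.250)
contrast -0.208 (-0.224, -0.188)  band 2-4  p_weekday < 1e-300  p_weekend 5e-164
```

against ground truth medians 05:00 / 07:00, AMRs 0.441 / 0.233 and contrast
−0.208: peak times recovered to minutes, cyclic-strength measures to the
third decimal, and both day-types are (correctly) declared significantly
diurnal at the P < .001 rule. The negative contrast says the weekday cycle
is the stronger one. `run_analysis(run_config(...))` wraps these steps and
writes a summary CSV, a run manifest, polar figures and a stage log.

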