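---
title: "Modelling diurnal and day-of-week rhythms in hourly search-interest series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diurnal and day-of-week rhythms in hourly search-interest series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hourly relative search volume (RSV) for a health-related query — the kind of
series Google Trends returns for a term, a region and a year — mixes several
signals: a slowly varying secular trend, a strong 24-hour cycle whose shape
differs between weekdays and weekend days, occasional epidemics or
media-driven surges, and sampling noise (Trends rescales a sampled query
share to 0–100 within each request window, so replicate downloads of the
same window differ). The scientific questions are *when in the day* interest
in a term peaks, *how strong* that daily cycle is, and whether weekday and
weekend behaviour differ — answered separately per term.

`searchcycles` implements that analysis as a reusable pipeline: a harmonic
(Serfling-type) regression with an embedded LASSO-selected outlier filter,
circular-statistical summaries of the fitted daily curves, and a
moving-block bootstrap for uncertainty.

## The model

For an hourly series \(y_x\) with local clock time \(t(x) \in [0, 24)\) and
elapsed time \(x\) in hours since local midnight, January 1 of the study
year, the mean model is

\[
E[y_x] \;=\; \beta_0 \;+\; \underbrace{\sum_{j=1}^{3} \gamma_j P_j(x/24)}_{\text{trend}}
\;+\; \underbrace{\sum_{d \in \{\mathrm{wd},\mathrm{we}\}} \mathbb{1}\{d(x)\}
\sum_{n=1}^{4}\big[a_{d,n}\sin(n\omega t) + b_{d,n}\cos(n\omega t)\big]}_{\text{diurnal harmonics}}
\;+\; \delta\,\mathbb{1}\{\mathrm{we}(x)\}
\;+\; \underbrace{\sum_{(k,m) \in S} \eta_{k,m}\,\mathbb{1}\{km \le x \le k(m{+}1)-1\}}_{\text{outlier indicators}},
\]

with \(\omega = 2\pi/24\). The pieces:

* **Trend.** \(P_1,P_2,P_3\) are orthogonal polynomials of degree 1–3 in
  elapsed days, orthonormalized on the observed rows (QR of the centered
  Vandermonde matrix, as `stats::poly()` computes). Slow seasonal drift is
  absorbed here; there are deliberately no annual-period harmonics.
* **Day-type harmonics.** Four sine/cosine pairs per day-type give each of
  the weekday and weekend curves its own shape up to the 4th daily Fourier
  component. A free weekend *level* term \(\delta\) is included as well:
  "separate diurnal effects" must free the weekend curve's mean, not only
  its shape, otherwise the weekend amplitude-to-mean ratio is not identified
  by the fit.
* **Outlier indicators.** For each window width
  \(k \in \{8, 16, 32, 64, 128, 168\}\) hours (plus two alternative preset
  sets for sensitivity analysis) the 0/1 indicators of consecutive windows
  tile the year. These absorb epidemics and other localized, non-periodic
  departures. Including all \(\approx 2200\) of them would be
  non-identifiable, so a cross-validated LASSO selects a small subset
  \(S\) first, and the final coefficients are then estimated by ordinary
  least squares on intercept + trend + harmonics + the selected indicators.

### Why only the indicators are penalized

The harmonic and trend coefficients are the quantities of scientific
interest; shrinking them would bias every downstream summary. The LASSO
penalty is therefore applied to the indicator columns only (the unpenalized
blocks always stay in the model). Indicator columns are rescaled to unit
Euclidean norm inside the LASSO — a 168-hour window otherwise carries
\(\sqrt{21}\) times the norm of an 8-hour window and is effectively
under-penalized — while reported coefficients are on the original 0/1 scale.
The penalty is chosen by 10-fold cross-validation with the one-standard-error
rule (the sparsest penalty within one SE of the CV minimum), which keeps the
selected set small.

### Why CV folds are assigned at random

Fold assignment is random by default rather than contiguous blocks. This was
a genuinely open design point and we initially expected contiguous folds to
be the safer choice for a time series. Implementation proved otherwise: a
localized indicator column is nonzero only on one short stretch of the
series, so with contiguous folds the entire support of a true surge column
sits inside a single fold; whenever that fold is held out, the column is
all-zero in the training data, its coefficient cannot be estimated, and the
column can never reduce cross-validation error. In simulation a +60, 8-hour
surge was then *never* selected under the one-SE rule (0/10 seeds), while
random fold assignment selected exactly the covering column in 10/10 seeds
with no spurious picks. Random folds are harmless for the independent-noise
data the generator produces; for strongly autocorrelated residuals a
`fold_scheme = "contiguous"` option remains available.

### Collinearity and tie-breaking

Exactly collinear selected indicators (e.g. a 16-hour window together with
the two 8-hour windows that tile it) are resolved by keeping the narrowest
width, then the earliest window — the most local explanation of an outlier —
and dropping the rest with a warning.

## Summaries of the fitted curves

All summaries are functions of the fitted *diurnal curve* of a day-type: the
model's mean evaluated on a 1-minute clock grid with the trend frozen at the
study-midpoint day (any fixed day gives the same harmonics; the midpoint
centers the level, and peak times are conventionally reported to
the minute).

* **Amplitude-to-mean ratio (AMR).** Peak-to-trough range divided by the
  curve mean; 0 for a flat curve, dimensionless, invariant to time shifts
  and to rescaling the curve.
* **Circular median time.** The curve minimum is subtracted and the
  remainder treated as a nonnegative weight density on the 24-hour circle;
  the statistic is the grid point minimizing the weighted mean shorter-arc
  distance, ties broken toward the earliest clock time. Min-subtraction
  makes the statistic invariant to the baseline level and peak-seeking: for
  a unimodal curve it lands on the peak. (A weighted circular median was
  chosen over the circular mean because it is robust to secondary bumps in
  multimodal profiles.)
* **Weekday–weekend contrast.** Difference of the two ranges divided by the
  average of the two curve means; negative values mean stronger weekday
  cyclicity. This is *not* the difference of the two AMRs — the common
  denominator avoids conflating level and amplitude differences.
* **Peak-time difference bands.** Weekday-vs-weekend median differences are
  reported as the shorter-arc circular difference bucketed into 2-hour bands
  ("0-2" … "10-12"). The shorter arc is the standard circular convention;
  note that for times almost 11 h apart the *longer* arc crosses fewer
  calendar-day boundaries, so tables built by naive subtraction can differ.

## Uncertainty

Standard errors, confidence intervals and P values come from a residual-based
circular moving-block bootstrap with a fixed 20-hour block width: blocks of
OLS residuals are resampled with uniformly random, wrap-around start
positions, concatenated, truncated to the series length, and added back to
the *outlier-free* fitted values. Residual (rather than whole-series)
resampling preserves the deterministic design — the weekday/weekend
alternation and the trend — which resampling raw blocks would scramble. The
LASSO support is held fixed across replicates: re-selection per replicate is
unstable, roughly a thousand times more costly, and irrelevant to the
harmonic block the summaries depend on. Each replicate refits the OLS
coefficients and recomputes every summary.

* Percentile intervals are reported for AMRs and the contrast; median times
  get arc-based percentile intervals (deviations from the point estimate
  folded into \((-12, 12]\) hours).
* The diurnality test per day-type is a Wald-type statistic on the eight
  harmonic coefficients, using the bootstrap covariance. With \(B\)
  replicates the covariance estimate is Wishart-noisy, so the statistic is
  referenced to its finite-replicate Hotelling form,
  \(\frac{B-d}{d(B-1)}\,T \sim F(d,\,B-d)\) with \(d = 8\), which converges
  to the usual \(\chi^2_8\) reference as \(B\) grows but holds its level at
  the smaller \(B\) used in fast runs. Significance is declared at
  \(P < 0.001\).
* Every replicate is reproducible in isolation: all randomness derives from
  `(seed, replicate)`.

## The synthetic generator

`synthetic_spec()` / `simulate_series()` generate Trends-like hourly series
with known ground truth: baseline + cubic trend + day-type harmonic sets +
additive boxcar surges + Gaussian noise, clipped at zero, with optional
per-week renormalization to max 100 emulating Trends' independent scaling of
each one-week request. The ground-truth record stores the noiseless weekday
and weekend curves and their circular medians and AMRs, computed by the same
circular-summary operations used on fitted models, so recovery tests compare
like with like.

Default study conditions (chosen once, as a realistic stand-in for a
combined multi-state series of a strongly diurnal health term): one year of
hourly data (n = 8760), baseline 50 RSV units, weekday harmonics of
amplitude 10 (order 1) and 3 (order 2), a weekend first harmonic of
amplitude 6, noise sd 5, and — in outlier scenarios — a +60 surge lasting
8 hours. Boxcar surges are exactly the shape the indicator basis can absorb,
which makes the filter directly testable; real epidemics ramp up and decay,
so real-data filtering is necessarily less clean than the tests suggest.
What the generator deliberately does *not* model: Google's sampling
algorithm and query-share denominator, integer quantization (optional),
sub-hourly structure, and autocorrelated noise.

## Numerical choices and degenerate inputs

* Curve grid: 1 minute (1440 points); medians are reported to the minute.
  Calibration studies use a coarser 10-minute grid for speed — for smooth
  4-harmonic curves the induced AMR error is below \(10^{-3}\).
* Circular-median costs are compared after rounding to \(10^{-12}\) to make
  the earliest-time tie-break robust to floating-point noise.
* A constant curve has no defined median (error); a curve with nonpositive
  mean has no defined AMR (error).
* Missing hours are left as gaps and excluded from fitting; indicator
  windows are anchored on elapsed hours, so gaps do not shift windows.
* DST transitions follow the IANA zone database; the duplicated/missing
  local hour (2 hours a year) is kept as-is.
* An all-zero week cannot be rescaled to max 100 and is left all-zero.
* A degenerate bootstrap distribution (all replicates identical, e.g. from
  a noiseless fit) is flagged and collapses the CIs to a point.

## Problem sizes used by the test-suite studies

The bootstrap calibration study runs 300 coverage simulations and 400 null
simulations at n = 8760 with 200 bootstrap replicates each (scaled down from
the 1000-replicate analysis default), 5 CV folds and a 40-point penalty
path; the surge-recovery study uses 50 seeds. These sizes were chosen to
keep a full run on one CPU in the tens of minutes while leaving Monte-Carlo
error well below the tolerances being checked.

## Known limitations

* A surge that straddles indicator-window boundaries is absorbed by a wider
  window and leaks partially into the harmonics; the filter is most
  effective for departures the window grid can represent.
* A brief surge biases a curve's peak-to-trough range and its mean in the
  same direction, so its net effect on the amplitude-to-mean *ratio* is
  partially self-cancelling and can be small relative to sampling noise —
  the filter's benefit shows most clearly on the harmonic coefficients
  themselves.
* Weekly renormalization (`per_week_rescale`) is a multiplicative distortion
  the additive indicator basis can only approximate; replicate averaging and
  multi-state pooling attenuate it in practice.
* The bootstrap assumes the 20-hour block captures the residual dependence;
  strongly autocorrelated residuals beyond that horizon would need a longer
  block.
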