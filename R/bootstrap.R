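#' Block-bootstrap configuration
#'
#' @param block_hours fixed block width in hours (default 20).
#' @param n_reps number of bootstrap replicates (default 1000).
#' @param seed integer seed; all replicate randomness derives from
#'   `(seed, rep)` so any replicate can be reproduced in isolation.
#' @param ci_level two-sided confidence level (default 0.95).
#' @return object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(block_hours = 20L, n_reps = 1000L, seed = 1L,
                             ci_level = 0.95) {
  stopifnot(block_hours >= 1, n_reps >= 2, ci_level > 0, ci_level < 1)
  structure(list(block_hours = as.integer(block_hours),
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 ci_level = ci_level), class = "bootstrap_config")
}

# Circular moving-block index vector for one replicate: ceil(n/L) uniform
# start positions, blocks wrap at the series end, concatenation truncated to n.
resample_indices <- function(n, block_hours, seed, rep) {
  L <- block_hours
  nb <- ceiling(n / L)
  starts <- with_seed(derive_seed(seed, "boot", rep),
                      sample.int(n, nb, replace = TRUE))
  idx <- outer(0:(L - 1), starts, "+")        # L x nb, 0-based offsets
  (as.integer(idx) %% n + 1L)[seq_len(n)]
}

#' Circular moving-block resample of a series
#'
#' Draws `ceiling(n / block_hours)` block start positions uniformly (blocks
#' wrap past the series end), concatenates the blocks and truncates to the
#' original length. Used on model residuals inside [bootstrap_summaries()];
#' exposed for diagnostics.
#'
#' @param x numeric vector to resample.
#' @param config a [bootstrap_config()].
#' @param rep replicate number (>= 1); with the config seed it fully
#'   determines the resample.
#' @return numeric vector, `length(x)`.
#' @export
block_resample <- function(x, config = bootstrap_config(), rep = 1L) {
  n <- length(x)
  if (n < config$block_hours) stop("series shorter than one block")
  x[resample_indices(n, config$block_hours, config$seed, rep)]
}

# Solve V^{-1} b robustly (pseudo-inverse fallback for near-singular V).
wald_quad <- function(b, V) {
  q <- tryCatch(sum(b * solve(V, b)), error = function(e) NA_real_)
  if (!is.finite(q)) {
    s <- svd(V)
    pos <- s$d > max(s$d) * 1e-10
    q <- sum((crossprod(s$u[, pos, drop = FALSE], b))^2 / s$d[pos])
  }
  q
}

#' Bootstrap confidence intervals and P values for the diurnal summaries
#'
#' Residual-based circular moving-block bootstrap of a fitted model: blocks of
#' residuals are resampled and added back to the outlier-free fitted values,
#' the OLS fit is recomputed on every replicate with the nuisance support held
#' fixed at the original LASSO selection, and all summaries (circular median
#' times, amplitude-to-mean ratios, weekday-weekend contrast) are recomputed.
#' Percentile intervals are reported for the ratios and the contrast;
#' arc-based circular percentile intervals for the median times. Diurnality
#' P values come from a Wald-type statistic on each day-type's eight harmonic
#' coefficients using the bootstrap covariance, referenced to its
#' finite-replicate F distribution (`F(d, B - d)` after the Hotelling scaling
#' `(B - d) / (d (B - 1))`, which tends to the chi-square reference as the
#' replicate count B grows).
#'
#' @param model a `serfling_fit`.
#' @param config a [bootstrap_config()].
#' @param term label copied into the summary row.
#' @param step_min diurnal-curve grid resolution in minutes.
#' @param keep_replicates attach the per-replicate statistics as attribute
#'   `"replicates"` (for audit dumps).
#' @return a one-row `diurnal_summary` tibble: point estimates, CI bounds,
#'   bootstrap SEs, P values, and the peak-time difference band.
#' @export
bootstrap_summaries <- function(model, config = bootstrap_config(),
                                term = "series", step_min = 1,
                                keep_replicates = FALSE) {
  stopifnot(inherits(model, "serfling_fit"), inherits(config, "bootstrap_config"))
  n <- model$design$n
  R <- config$n_reps
  resid <- model$residuals
  base <- model$fitted_clean
  idx <- vapply(seq_len(R), function(r)
    resample_indices(n, config$block_hours, config$seed, r), integer(n))
  Ystar <- base + matrix(resid[idx], n, R)
  B <- qr.coef(model$qr, Ystar)
  rownames(B) <- model$coef_names

  grid <- seq(0, 24 - step_min / 60, by = step_min / 60)
  D <- circ_dist_matrix(grid)
  tmid <- predict_trend_basis(model$design$trend_coefs, model$design$mid_day)
  trend_mid_r <- as.numeric(tmid %*% B[paste0("trend", 1:3), , drop = FALSE])

  per_daytype <- function(daytype) {
    G <- harmonic_grid_matrix(grid, daytype)
    Bh <- B[colnames(G), , drop = FALSE]
    level_r <- B["(Intercept)", ] + trend_mid_r +
      if (daytype == "weekend") B["weekend_level", ] else 0
    curves <- G %*% Bh + matrix(level_r, length(grid), R, byrow = TRUE)
    mins <- apply(curves, 2, min)
    maxs <- apply(curves, 2, max)
    means <- colMeans(curves)
    W <- sweep(curves, 2, mins)
    cost <- D %*% W
    med_r <- grid[max.col(-t(cost), ties.method = "first")]
    list(amr = (maxs - mins) / means, med = med_r,
         rng = maxs - mins, mean = means, Bh = Bh)
  }
  wd <- per_daytype("weekday")
  we <- per_daytype("weekend")
  contrast_r <- (we$rng - wd$rng) / ((we$mean + wd$mean) / 2)

  a <- (1 - config$ci_level) / 2
  ci <- function(x) unname(stats::quantile(x, c(a, 1 - a)))
  circ_ci <- function(reps, center) {
    dev <- ((reps - center + 12) %% 24) - 12
    (center + unname(stats::quantile(dev, c(a, 1 - a)))) %% 24
  }
  pval <- function(daytype, Bh) {
    b0 <- model$harmonic_coeffs[rownames(Bh)]
    V <- stats::cov(t(Bh))
    d <- length(b0)
    if (R <= d || max(abs(V)) == 0) return(NA_real_)
    Tq <- wald_quad(as.numeric(b0), V)
    stats::pf(Tq * (R - d) / (d * (R - 1)), d, R - d, lower.tail = FALSE)
  }

  cw <- diurnal_curve(model, "weekday", step_min)
  ce <- diurnal_curve(model, "weekend", step_min)
  med0_w <- circular_median_time(cw)
  med0_e <- circular_median_time(ce)
  amr0_w <- amplitude_mean_ratio(cw)
  amr0_e <- amplitude_mean_ratio(ce)
  con0 <- amr_contrast(model, step_min)

  degenerate <- stats::sd(wd$amr) < 1e-10 && stats::sd(we$amr) < 1e-10
  if (degenerate) warning("degenerate bootstrap distribution: CIs collapse to a point")

  ciw <- circ_ci(wd$med, med0_w); cie <- circ_ci(we$med, med0_e)
  aw <- ci(wd$amr); ae <- ci(we$amr); cc <- ci(contrast_r)
  out <- tibble::tibble(
    term = term,
    median_weekday = med0_w, median_weekday_lo = ciw[1], median_weekday_hi = ciw[2],
    median_weekend = med0_e, median_weekend_lo = cie[1], median_weekend_hi = cie[2],
    median_diff_band = median_diff_band(med0_w, med0_e),
    amr_weekday = amr0_w, amr_weekday_lo = aw[1], amr_weekday_hi = aw[2],
    amr_weekday_se = stats::sd(wd$amr),
    amr_weekend = amr0_e, amr_weekend_lo = ae[1], amr_weekend_hi = ae[2],
    amr_weekend_se = stats::sd(we$amr),
    amr_contrast = con0, amr_contrast_lo = cc[1], amr_contrast_hi = cc[2],
    amr_contrast_se = stats::sd(contrast_r),
    p_weekday = pval("weekday", wd$Bh),
    p_weekend = pval("weekend", we$Bh),
    n_reps = R, block_hours = config$block_hours,
    degenerate = degenerate)
  class(out) <- c("diurnal_summary", class(out))
  if (keep_replicates)
    attr(out, "replicates") <- tibble::tibble(
      rep = seq_len(R), amr_weekday = wd$amr, amr_weekend = we$amr,
      median_weekday = wd$med, median_weekend = we$med, contrast = contrast_r)
  out
}
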