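# Independent brute-force oracles and small fixture builders shared by the
# suite. The oracles deliberately use naive loops, not the package's vectorized
# code paths.

# Weighted circular median by exhaustive candidate search: for every candidate
# time, accumulate the weighted shorter-arc distance explicitly; strict
# improvement keeps the earliest candidate on ties.
brute_circ_median <- function(times, weights) {
  best <- Inf
  arg <- NA_real_
  for (cand in times) {
    s <- 0
    for (i in seq_along(times)) {
      d <- abs(times[i] - cand)
      if (d > 12) d <- 24 - d
      s <- s + weights[i] * d
    }
    if (s < best * (1 - 1e-12)) {
      best <- s
      arg <- cand
    }
  }
  arg
}

# A curve object on an arbitrary grid without going through a fitted model.
make_curve <- function(values, grid = seq(0, 24 - 1 / 60, by = 1 / 60),
                       daytype = "weekday") {
  structure(list(daytype = daytype, grid = grid, values = values),
            class = "diurnal_curve")
}

harm_names <- unlist(lapply(c("weekday", "weekend"), function(dt)
  as.vector(rbind(sprintf("%s_sin_%d", dt, 1:4), sprintf("%s_cos_%d", dt, 1:4)))))

# Minimal serfling_fit stand-in with zero trend, for closed-form curve tests.
fake_model <- function(intercept = 10, coefs = c(), weekend_level = 0) {
  hb <- stats::setNames(numeric(16), harm_names)
  hb[names(coefs)] <- coefs
  design <- list(trend_coefs = attr(stats::poly(0:9, 3), "coefs"),
                 mid_day = 4.5, n = 10L)
  structure(list(intercept = intercept,
                 trend_coeffs = stats::setNames(c(0, 0, 0), paste0("trend", 1:3)),
                 harmonic_coeffs = hb, weekend_level = weekend_level,
                 design = design),
            class = "serfling_fit")
}

# Small constant-valued series for IO tests.
mk_series <- function(values, term = "t", loc = "NY", rep_id = 1L,
                      start = "2018-01-01 00:00:00") {
  hourly_series(term, loc,
                as.POSIXct(start, tz = "UTC") + 3600 * (seq_along(values) - 1),
                values, replicate = rep_id)
}

# Standard 8-week synthetic scenario used across fit/bootstrap unit tests.
demo_spec <- function(n_hours = 1344, noise_sd = 0, outliers = list(),
                      seed = 1, trend = c(0, 0, 0)) {
  synthetic_spec(n_hours = n_hours, baseline = 50, trend_coeffs = trend,
                 harmonics = list(
                   weekday = harmonic_set(c(1, 2), c(10, 3), peak_hour = c(5, 2)),
                   weekend = harmonic_set(1, 6, peak_hour = 7)),
                 noise_sd = noise_sd, outliers = outliers, seed = seed)
}
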