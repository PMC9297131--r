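#' Specify a harmonic set for one day-type
#'
#' Convenience constructor for the per-day-type harmonic list of a
#' [synthetic_spec()]. Each harmonic contributes
#' `amplitude * cos(n * omega * t - phase)` with `omega = 2*pi/24`, so a
#' harmonic peaks at local hour `peak_hour` when `phase = n * omega * peak_hour`.
#'
#' @param n integer harmonic orders (1..4).
#' @param amplitude nonnegative amplitudes, recycled against `n`.
#' @param peak_hour local hour of the cosine peak (used to derive the phase);
#'   give either this or `phase`.
#' @param phase phase in radians, wrapped into `[0, 2*pi)`.
#' @return data frame with columns `n`, `amplitude`, `phase`.
#' @export
harmonic_set <- function(n, amplitude, peak_hour = NULL, phase = NULL) {
  if (is.null(phase)) {
    if (is.null(peak_hour)) stop("give peak_hour or phase")
    phase <- n * OMEGA * peak_hour
  }
  data.frame(n = as.integer(n), amplitude = as.numeric(amplitude),
             phase = as.numeric(phase) %% (2 * pi))
}

#' Ground-truth parameters for a synthetic Trends-like series
#'
#' Defines the generative model
#' `rsv(x) = clip0[ baseline + trend(x/24) + harmonics(daytype(x), t(x)) +
#' surges(x) + N(0, noise_sd) ]` on an hourly grid, where `trend` is a cubic in
#' elapsed days, the weekday and weekend day-types carry separate harmonic
#' sets (orders 1..4), and surges are additive boxcar outliers — exactly the
#' components the downstream regression is built to estimate or filter.
#'
#' @param n_hours series length (default one year, 8760).
#' @param baseline mean RSV level.
#' @param trend_coeffs length-3 numeric: coefficients of `d, d^2, d^3` in
#'   elapsed days.
#' @param harmonics list with elements `weekday` and `weekend`, each a data
#'   frame from [harmonic_set()] (or `NULL` for none).
#' @param noise_sd standard deviation of the additive Gaussian noise (>= 0).
#' @param outliers list of `c(start_hour, duration_hours, magnitude)` boxcar
#'   surges (start in elapsed hours since the series origin, 0-based).
#' @param per_week_rescale emulate Trends' independent per-request scaling by
#'   renormalizing each 168-h window to max 100 (see [apply_weekly_rescale()]).
#' @param seed integer RNG seed for the noise.
#' @param start first timestamp (UTC), default `"2018-01-01 00:00:00"`.
#' @param term,location labels for the generated series.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_hours = 8760, baseline = 50,
                           trend_coeffs = c(0, 0, 0),
                           harmonics = list(weekday = NULL, weekend = NULL),
                           noise_sd = 0, outliers = list(),
                           per_week_rescale = FALSE, seed = 1L,
                           start = "2018-01-01 00:00:00",
                           term = "synthetic", location = "SIM") {
  if (noise_sd < 0) stop("negative noise_sd")
  stopifnot(length(trend_coeffs) == 3, n_hours >= 1)
  for (o in outliers) {
    stopifnot(length(o) == 3)
    if (o[2] < 1) stop("outlier duration_hours must be >= 1")
  }
  structure(list(n_hours = as.integer(n_hours), baseline = baseline,
                 trend_coeffs = as.numeric(trend_coeffs),
                 harmonics = harmonics, noise_sd = noise_sd,
                 outliers = outliers, per_week_rescale = per_week_rescale,
                 seed = as.integer(seed), start = start,
                 term = term, location = location),
            class = "synthetic_spec")
}

# Sum of one day-type's harmonic terms at clock hours t.
harmonic_value <- function(hset, t) {
  if (is.null(hset) || !nrow(hset)) return(numeric(length(t)) + 0)
  v <- numeric(length(t))
  for (i in seq_len(nrow(hset)))
    v <- v + hset$amplitude[i] * cos(hset$n[i] * OMEGA * t - hset$phase[i])
  v
}

#' Simulate an hourly RSV series with known ground truth
#'
#' Generates one annotated [hourly_series] from a [synthetic_spec()] together
#' with a ground-truth record: the noiseless weekday and weekend diurnal
#' curves (evaluated at the mid-study trend level on a 1-minute grid) and
#' their true circular median times and amplitude-to-mean ratios, computed
#' with the same circular-summary operations applied to fitted models so that
#' recovery tests compare like with like.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `series` (annotated `hourly_series`) and `truth`
#'   (list: `curve_weekday`, `curve_weekend`, `median_weekday`,
#'   `median_weekend`, `amr_weekday`, `amr_weekend`, `amr_contrast`, `spec`).
#' @export
simulate_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_hours
  ts <- as.POSIXct(spec$start, tz = "UTC") + 3600 * (0:(n - 1))
  ann <- local_annotations(ts, "UTC")
  d <- ann$elapsed_days
  trend <- spec$trend_coeffs[1] * d + spec$trend_coeffs[2] * d^2 +
    spec$trend_coeffs[3] * d^3
  harm <- ifelse(ann$is_weekend,
                 harmonic_value(spec$harmonics$weekend, ann$hour_of_day),
                 harmonic_value(spec$harmonics$weekday, ann$hour_of_day))
  surge <- numeric(n)
  for (o in spec$outliers) {
    idx <- which(ann$elapsed_hours >= o[1] & ann$elapsed_hours <= o[1] + o[2] - 1)
    surge[idx] <- surge[idx] + o[3]
  }
  noise <- if (spec$noise_sd > 0)
    with_seed(derive_seed(spec$seed, "sim"), rnorm(n, 0, spec$noise_sd))
  else numeric(n)
  y <- pmax(spec$baseline + trend + harm + surge + noise, 0)
  series <- hourly_series(spec$term, spec$location, ts, y, replicate = 1L)
  series <- dplyr::bind_cols(series, ann)   # already the UTC local annotations
  class(series) <- unique(c("hourly_series", class(series)))
  attr(series, "zone") <- "UTC"
  if (spec$per_week_rescale) series <- apply_weekly_rescale(series)

  mid_d <- mean(range(d))
  level <- spec$baseline + spec$trend_coeffs[1] * mid_d +
    spec$trend_coeffs[2] * mid_d^2 + spec$trend_coeffs[3] * mid_d^3
  grid <- seq(0, 24 - 1 / 60, by = 1 / 60)
  truth_curve <- function(daytype) {
    structure(list(daytype = daytype, grid = grid,
                   values = level + harmonic_value(spec$harmonics[[daytype]], grid)),
              class = "diurnal_curve")
  }
  cw <- truth_curve("weekday"); ce <- truth_curve("weekend")
  amr_w <- amplitude_mean_ratio(cw)
  amr_e <- amplitude_mean_ratio(ce)
  truth <- list(
    curve_weekday = cw, curve_weekend = ce,
    median_weekday = if (diff(range(cw$values)) > 0) circular_median_time(cw) else NA_real_,
    median_weekend = if (diff(range(ce$values)) > 0) circular_median_time(ce) else NA_real_,
    amr_weekday = amr_w, amr_weekend = amr_e,
    amr_contrast = (diff(range(ce$values)) - diff(range(cw$values))) /
      mean(c(mean(ce$values), mean(cw$values))),
    spec = spec
  )
  list(series = series, truth = truth)
}

#' Rescale each week of a series to maximum 100
#'
#' Emulates the fact that each Trends Historical Hourly Interest request
#' returns one week scaled independently to a 0..100 range. Within every
#' consecutive 168-hour window the values are multiplied by `100 / max`;
#' all-zero weeks are left untouched.
#'
#' @param series an [hourly_series].
#' @param integerize round to integers after scaling (as raw Trends does).
#' @return the rescaled series.
#' @export
apply_weekly_rescale <- function(series, integerize = FALSE) {
  stopifnot(nrow(series) >= 1)
  wk <- (seq_len(nrow(series)) - 1) %/% 168
  for (w in unique(wk)) {
    i <- which(wk == w)
    mx <- max(series$rsv[i])
    if (mx > 0) series$rsv[i] <- series$rsv[i] * (100 / mx)
  }
  if (integerize) series$rsv <- round(series$rsv)
  series
}
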