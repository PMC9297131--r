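#' Fitted diurnal curve for one day-type
#'
#' Evaluates the model's mean RSV as a pure function of clock time on a
#' 1-minute grid: intercept + trend at the study-midpoint day (+ weekend level
#' for the weekend curve) + the day-type's four harmonic pairs. Evaluating the
#' trend at a single fixed day makes the curve depend on clock time only; the
#' midpoint centers the level over the study period.
#'
#' @param model a `serfling_fit`.
#' @param daytype `"weekday"` or `"weekend"`.
#' @param step_min grid resolution in minutes (default 1).
#' @return object of class `diurnal_curve`: list `daytype`, `grid` (hours in
#'   `[0, 24)`), `values`.
#' @export
diurnal_curve <- function(model, daytype = c("weekday", "weekend"),
                          step_min = 1) {
  daytype <- match.arg(daytype)
  grid <- seq(0, 24 - step_min / 60, by = step_min / 60)
  G <- harmonic_grid_matrix(grid, daytype)
  hb <- model$harmonic_coeffs[colnames(G)]
  tmid <- predict_trend_basis(model$design$trend_coefs, model$design$mid_day)
  level <- model$intercept + sum(tmid * model$trend_coeffs) +
    if (daytype == "weekend") model$weekend_level else 0
  structure(list(daytype = daytype, grid = grid,
                 values = as.numeric(level + G %*% hb)),
            class = "diurnal_curve")
}

# sin/cos columns of one day-type evaluated on a clock-time grid.
harmonic_grid_matrix <- function(grid, daytype) {
  G <- sapply(1:4, function(k) cbind(sin(k * OMEGA * grid), cos(k * OMEGA * grid)))
  dim(G) <- c(length(grid), 8)
  colnames(G) <- as.vector(rbind(sprintf("%s_sin_%d", daytype, 1:4),
                                 sprintf("%s_cos_%d", daytype, 1:4)))
  G
}

#' Amplitude-to-mean ratio of a diurnal curve
#'
#' Peak-to-trough range divided by the mean value over the grid; a unitless
#' measure of diurnal cyclic strength (0 for a flat curve).
#'
#' @param curve a [diurnal_curve()] or a numeric vector of curve values.
#' @return nonnegative real.
#' @export
amplitude_mean_ratio <- function(curve) {
  v <- if (inherits(curve, "diurnal_curve")) curve$values else as.numeric(curve)
  m <- mean(v)
  if (m <= 0) stop("undefined statistic: curve mean <= 0")
  (max(v) - min(v)) / m
}

# Weighted circular median on a clock grid: the grid point minimizing the
# weighted mean shorter-arc distance to all grid points, ties -> earliest.
# `cost = D %*% w` with D the pairwise arc-distance matrix.
circ_median_weighted <- function(grid, weights) {
  D <- circ_dist_matrix(grid)
  cost <- as.numeric(D %*% weights)
  grid[which.min(round(cost / sum(weights), 12))]
}

# Pairwise shorter-arc distances (hours) between grid points; symmetric.
# Memoized: the same 1-minute grid is used by every curve summary.
.circ_cache <- new.env(parent = emptyenv())
circ_dist_matrix <- function(grid) {
  key <- sprintf("g%d_%.8f_%.8f", length(grid), grid[1], grid[length(grid)])
  if (!is.null(.circ_cache[[key]])) return(.circ_cache[[key]])
  d <- abs(outer(grid, grid, "-"))
  d <- pmin(d, 24 - d)
  if (length(grid) <= 1500) .circ_cache[[key]] <- d
  d
}

#' Circular median time of a diurnal curve
#'
#' The curve minimum is subtracted and the remainder treated as a nonnegative
#' weight density on the 24-hour circle; the statistic is the grid point
#' minimizing the weighted mean arc distance (the weighted circular median),
#' with ties broken by the earliest clock time. Min-subtraction makes the
#' statistic invariant to the baseline level and peak-seeking: for a unimodal
#' curve it reflects the peak occurrence time.
#'
#' @param curve a [diurnal_curve()].
#' @return decimal hours in `[0, 24)`; format with [format_clock()].
#' @export
circular_median_time <- function(curve) {
  v <- curve$values
  w <- v - min(v)
  if (all(w < 1e-12 * max(abs(v), 1))) stop("undefined statistic: constant curve")
  circ_median_weighted(curve$grid, w)
}

#' Weekday-weekend amplitude contrast
#'
#' Difference of the weekend and weekday peak-to-trough amplitudes divided by
#' the average of the two curve means. Negative values indicate stronger
#' weekday cyclic strength, positive values stronger weekend cyclic strength.
#'
#' @param model a `serfling_fit`.
#' @param step_min curve grid resolution in minutes.
#' @return real; sign convention as above.
#' @export
amr_contrast <- function(model, step_min = 1) {
  cw <- diurnal_curve(model, "weekday", step_min)
  ce <- diurnal_curve(model, "weekend", step_min)
  mw <- mean(cw$values); me <- mean(ce$values)
  if ((mw + me) / 2 <= 0) stop("undefined statistic: nonpositive average mean")
  (diff(range(ce$values)) - diff(range(cw$values))) / mean(c(mw, me))
}

#' Band label for the weekday-weekend peak-time difference
#'
#' Shorter-arc circular difference between two clock times, bucketed into
#' 2-hour bands `"0-2", "2-4", ..., "10-12"`.
#'
#' @param m1,m2 clock times (`"hh:mm"` or decimal hours).
#' @return character band label.
#' @export
median_diff_band <- function(m1, m2) {
  d <- circ_diff_hours(m1, m2)
  lo <- pmin(2 * floor(d / 2), 10)
  sprintf("%d-%d", lo, lo + 2)
}

#' Normalize hourly means for polar plotting
#'
#' Divides each hourly mean by the smallest one, so the quietest hour maps to
#' exactly 1.0 (plotted nearest the center) and other hours to their relative
#' search interest.
#'
#' @param hourly_means numeric vector (typically 24 values), all positive.
#' @return numeric vector with minimum exactly 1.
#' @export
polar_normalize <- function(hourly_means) {
  mn <- min(hourly_means)
  if (mn <= 0) stop("polar normalization requires strictly positive values")
  hourly_means / mn
}
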