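#' Nuisance-width presets
#'
#' The default interval-width set for the outlier indicator basis and the two
#' alternative sets used for sensitivity analysis. All three end in 168 h
#' (one week, the length of a single Trends request window).
#' @export
width_presets <- list(
  default       = c(8L, 16L, 32L, 64L, 128L, 168L),
  sensitivity_a = c(7L, 14L, 28L, 56L, 112L, 168L),
  sensitivity_b = c(9L, 18L, 36L, 72L, 144L, 168L)
)

#' Orthogonal cubic trend basis
#'
#' Degree 1-3 orthogonal polynomial columns in elapsed days, orthonormalized
#' on the observed rows (QR of the centered Vandermonde matrix, as
#' [stats::poly()] computes); the constant is left to the model intercept.
#' The prediction coefficients are attached so the trend can be evaluated at
#' any day (e.g. the study midpoint when forming diurnal curves).
#'
#' @param elapsed_days numeric vector of elapsed days since the series origin.
#' @return n x 3 matrix with columns `trend1..trend3` and attribute `coefs`.
#' @export
build_trend_basis <- function(elapsed_days) {
  if (!all(is.finite(elapsed_days))) stop("non-finite elapsed_days")
  if (length(unique(elapsed_days)) < 4)
    stop("rank error: need at least 4 distinct elapsed_days values")
  p <- stats::poly(elapsed_days, degree = 3)
  m <- unclass(p)[, 1:3, drop = FALSE]
  colnames(m) <- paste0("trend", 1:3)
  attr(m, "coefs") <- attr(p, "coefs")
  m
}

# Evaluate the trend basis at new day values using the stored coefficients.
predict_trend_basis <- function(coefs, elapsed_days) {
  p <- stats::poly(elapsed_days, degree = 3, coefs = coefs)
  m <- unclass(p)[, 1:3, drop = FALSE]
  colnames(m) <- paste0("trend", 1:3)
  m
}

#' Day-type-specific diurnal harmonic basis
#'
#' For each row, `sin(n*omega*t)` and `cos(n*omega*t)` (`omega = 2*pi/24`,
#' `n = 1..4`) are placed in the columns of the row's day-type (weekday or
#' weekend); the other day-type's eight columns are zero. A 0/1
#' weekend-level column is appended so the weekend curve's mean level is free,
#' not just its shape — without it the weekend amplitude-to-mean ratio would
#' not be identified.
#'
#' @param hour_of_day numeric vector of local clock hours in `[0, 24)`.
#' @param is_weekend logical vector, same length.
#' @return n x 17 matrix; columns `weekday_sin_1 .. weekend_cos_4,
#'   weekend_level`, with attribute `meta` describing each column.
#' @export
build_harmonic_basis <- function(hour_of_day, is_weekend) {
  if (any(hour_of_day < 0 | hour_of_day >= 24))
    stop("hour_of_day outside 0..23")
  stopifnot(length(hour_of_day) == length(is_weekend))
  n <- length(hour_of_day)
  H <- matrix(0, n, 17)
  nm <- character(17)
  meta <- NULL
  j <- 1
  for (dt in c("weekday", "weekend")) {
    rows <- if (dt == "weekend") is_weekend else !is_weekend
    for (k in 1:4) {
      H[rows, j]     <- sin(k * OMEGA * hour_of_day[rows])
      H[rows, j + 1] <- cos(k * OMEGA * hour_of_day[rows])
      nm[j]     <- sprintf("%s_sin_%d", dt, k)
      nm[j + 1] <- sprintf("%s_cos_%d", dt, k)
      meta <- rbind(meta,
                    data.frame(col = nm[c(j, j + 1)], daytype = dt, n = k,
                               fn = c("sin", "cos")))
      j <- j + 2
    }
  }
  H[, 17] <- as.numeric(is_weekend)
  nm[17] <- "weekend_level"
  colnames(H) <- nm
  attr(H, "meta") <- meta
  H
}

#' Interval-indicator nuisance basis
#'
#' For every width `k` in `widths` and window index `m = 0, 1, ...`, a 0/1
#' column equal to 1 exactly on hours `x` with `k*m <= x <= k*(m+1) - 1`.
#' For each width the windows partition the time axis (the truncated final
#' window is kept), so the columns of one width sum rowwise to exactly 1.
#' These are the candidate terms the LASSO filter chooses among to absorb
#' epidemics and other localized outliers.
#'
#' @param n_hours number of hours spanned (windows tile `0 .. n_hours-1`).
#' @param widths integer vector of window widths in hours (a [width_presets]
#'   entry by default).
#' @param x elapsed-hour value of each observed row (defaults to the full grid
#'   `0:(n_hours-1)`; pass the observed subset when the series has gaps).
#' @return sparse 0/1 `dgCMatrix` (rows = observations) with attribute `meta`,
#'   a data frame of `(col, width, m)`.
#' @export
build_nuisance_basis <- function(n_hours, widths = width_presets$default,
                                 x = 0:(n_hours - 1)) {
  if (any(widths <= 0)) stop("width <= 0")
  if (n_hours < max(widths)) stop("n_hours < max width")
  widths <- sort(unique(as.integer(widths)))
  # each hour x falls in exactly one window per width: window index x %/% k
  ii <- list(); jj <- list(); meta <- NULL; offset <- 0L
  for (w in seq_along(widths)) {
    k <- widths[w]
    mm <- 0:(ceiling(n_hours / k) - 1)
    ii[[w]] <- seq_along(x)
    jj[[w]] <- offset + (x %/% k) + 1L
    meta <- rbind(meta, data.frame(col = sprintf("k%d_m%d", k, mm),
                                   width = k, m = mm))
    offset <- offset + length(mm)
  }
  N <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                            dims = c(length(x), offset))
  colnames(N) <- meta$col
  attr(N, "meta") <- meta
  N
}

#' Build all design blocks for an annotated series
#'
#' Assembles the trend, harmonic and nuisance blocks on the observed rows of
#' a locally annotated [hourly_series], together with the metadata needed to
#' evaluate fitted diurnal curves later.
#'
#' @param series annotated `hourly_series` (see [to_local_time()]).
#' @param widths nuisance width set or the name of a [width_presets] entry.
#' @return object of class `design_matrices`: list with `trend`, `harmonic`,
#'   `nuisance`, their metadata, `hour_of_day`, `is_weekend`, `trend_coefs`,
#'   and `mid_day` (study mid-point in elapsed days).
#' @export
build_design <- function(series, widths = "default") {
  if (is.character(widths)) widths <- width_presets[[match.arg(widths, names(width_presets))]]
  if (!"elapsed_days" %in% names(series))
    stop("series must be annotated with to_local_time()")
  trend <- build_trend_basis(series$elapsed_days)
  harm <- build_harmonic_basis(series$hour_of_day, series$is_weekend)
  n_hours <- max(series$elapsed_hours) + 1L
  nuis <- build_nuisance_basis(n_hours, widths, x = series$elapsed_hours)
  structure(list(trend = trend, harmonic = harm, nuisance = nuis,
                 harmonic_meta = attr(harm, "meta"),
                 nuisance_meta = attr(nuis, "meta"),
                 widths = widths,
                 hour_of_day = series$hour_of_day,
                 is_weekend = series$is_weekend,
                 trend_coefs = attr(trend, "coefs"),
                 mid_day = mean(range(series$elapsed_days)),
                 n = nrow(series)),
            class = "design_matrices")
}
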