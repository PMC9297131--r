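#' Construct an hourly RSV series
#'
#' An `hourly_series` is a tibble holding one hourly relative-search-volume
#' (RSV) trace for a single (term, location, replicate) triple, with strictly
#' increasing hourly UTC timestamps. Raw Trends downloads are integers in
#' 0..100; replicate-averaged or location-combined series are real-valued.
#'
#' @param term search term (single string).
#' @param location region code, e.g. a US state abbreviation.
#' @param timestamp `POSIXct` vector (UTC), strictly increasing, hourly.
#' @param rsv nonnegative numeric vector, same length as `timestamp`.
#' @param replicate integer id of the download replicate (0 = averaged).
#' @param allow_gaps if `TRUE`, missing hours are permitted (steps may be any
#'   positive whole number of hours); otherwise the grid must be exactly hourly.
#' @return a tibble of class `hourly_series`.
#' @export
hourly_series <- function(term, location, timestamp, rsv, replicate = 1L,
                          allow_gaps = FALSE) {
  x <- tibble::tibble(
    term = as.character(term), location = as.character(location),
    replicate = as.integer(replicate), timestamp = timestamp,
    rsv = as.numeric(rsv)
  )
  class(x) <- c("hourly_series", class(x))
  attr(x, "allow_gaps") <- allow_gaps
  validate_hourly_series(x, allow_gaps = allow_gaps)
}

#' Validate the hourly-series invariants
#'
#' @param x a tibble with columns `term, location, replicate, timestamp, rsv`.
#' @param raw if `TRUE`, additionally require `rsv <= 100` (raw Trends scale).
#' @param allow_gaps permit missing hours (steps of whole multiples of 1 h).
#' @return `x` invisibly-validated (returned unchanged) or an error.
#' @export
validate_hourly_series <- function(x, raw = FALSE,
                                   allow_gaps = isTRUE(attr(x, "allow_gaps"))) {
  need <- c("term", "location", "replicate", "timestamp", "rsv")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("schema error: missing column(s) ", paste(miss, collapse = ", "))
  if (!inherits(x$timestamp, "POSIXct")) stop("schema error: timestamp must be POSIXct")
  if (anyNA(x$rsv)) stop("validation error: NA rsv at row(s) ",
                         paste(head(which(is.na(x$rsv)), 5), collapse = ", "))
  if (any(x$rsv < 0)) stop("validation error: negative rsv at row(s) ",
                           paste(head(which(x$rsv < 0), 5), collapse = ", "))
  if (raw && any(x$rsv > 100)) stop("validation error: raw rsv > 100 at row(s) ",
                                    paste(head(which(x$rsv > 100), 5), collapse = ", "))
  if (nrow(x) > 1) {
    dt <- diff(as.numeric(x$timestamp)) / 3600
    if (any(dt <= 0)) stop("validation error: non-monotone timestamps at row(s) ",
                           paste(head(which(dt <= 0) + 1, 5), collapse = ", "))
    bad <- if (allow_gaps) abs(dt - round(dt)) > 1e-9 else abs(dt - 1) > 1e-9
    if (any(bad)) stop("validation error: non-hourly step at row(s) ",
                       paste(head(which(bad) + 1, 5), collapse = ", "))
  }
  x
}

#' Read hourly RSV series from a long-format CSV
#'
#' Expects one row per (term, location, replicate, hour). Rows are split into
#' one [hourly_series] per (term, location, replicate).
#'
#' @param path CSV file path.
#' @param schema named character vector mapping the canonical names
#'   `term, location, timestamp, replicate, rsv` to the file's column names.
#' @param raw validate values on the raw 0..100 Trends scale.
#' @param tz time zone the file's timestamps are expressed in (default UTC).
#' @return named list of `hourly_series` (names `term|location|replicate`).
#' @export
read_series <- function(path,
                        schema = c(term = "term", location = "location",
                                   timestamp = "timestamp_utc",
                                   replicate = "replicate", rsv = "rsv"),
                        raw = FALSE, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(schema), names(df))
  if (length(miss)) stop("schema error: file lacks column(s) ", paste(miss, collapse = ", "))
  df <- df[, unname(schema)]
  names(df) <- names(schema)
  ts <- as.POSIXct(df$timestamp, tz = tz,
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d"))
  if (anyNA(ts)) stop("parse error: unparseable timestamp at row(s) ",
                      paste(head(which(is.na(ts)) + 1, 5), collapse = ", "))
  df$timestamp <- ts
  key <- interaction(df$term, df$location, df$replicate, drop = TRUE, sep = "|")
  out <- lapply(split(seq_len(nrow(df)), key), function(i) {
    d <- df[i, ][order(df$timestamp[i]), ]
    validate_hourly_series(
      hourly_series(d$term[1], d$location[1], d$timestamp, d$rsv,
                    replicate = d$replicate[1], allow_gaps = TRUE),
      raw = raw)
  })
  out[order(names(out))]
}

#' Write hourly series to the long CSV format
#'
#' @param x an `hourly_series` or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  if (inherits(x, "hourly_series")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(s)
    data.frame(term = s$term, location = s$location,
               timestamp_utc = format(s$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
               replicate = s$replicate,
               rsv = s$rsv)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Local-clock annotations for a vector of UTC instants in a given zone.
local_annotations <- function(timestamp, zone) {
  lt <- as.POSIXlt(timestamp, tz = zone)
  year0 <- lt$year[1] + 1900L
  origin <- as.POSIXct(sprintf("%d-01-01 00:00:00", year0), tz = zone)
  tibble::tibble(
    local_time = as.POSIXct(format(timestamp, tz = zone, usetz = FALSE), tz = "UTC"),
    hour_of_day = lt$hour,
    day_of_week = lt$wday,                       # 0 = Sunday .. 6 = Saturday
    is_weekend = lt$wday %in% c(0L, 6L),
    season = season_of_month(lt$mon + 1L),
    elapsed_hours = round(as.numeric(difftime(timestamp, origin, units = "hours"))),
    elapsed_days = round(as.numeric(difftime(timestamp, origin, units = "hours"))) / 24
  )
}

#' Annotate a series with local-time covariates
#'
#' Converts the UTC timestamps to a local IANA zone and attaches the covariates
#' used by the regression basis: local hour of day (`t` on the 24-h clock), day
#' of week, weekend indicator, meteorological season, and hours/days elapsed
#' since local midnight, January 1 of the series' first year (`x`, the nuisance
#' and trend covariate). DST transitions follow the zone database; the
#' duplicated or skipped local hour is kept as-is.
#'
#' @param series an [hourly_series].
#' @param zone IANA zone name, e.g. `"America/New_York"`.
#' @return the series with annotation columns added and attribute `zone` set.
#' @export
to_local_time <- function(series, zone) {
  if (!zone %in% OlsonNames()) stop("configuration error: unknown time zone '", zone, "'")
  ann <- local_annotations(series$timestamp, zone)
  out <- series[setdiff(names(series), names(ann))]
  out <- dplyr::bind_cols(out, ann)
  class(out) <- unique(c("hourly_series", class(out)))
  attr(out, "zone") <- zone
  attr(out, "allow_gaps") <- attr(series, "allow_gaps")
  out
}

#' Average replicate downloads of one term-location pair
#'
#' Google Trends resamples its query base per request, so replicate downloads
#' of the same window differ; averaging them pointwise reduces that sampling
#' noise. All replicates must share the same timestamp grid.
#'
#' @param series_list list of [hourly_series] replicates for one term-location.
#' @return one `hourly_series` with pointwise-mean `rsv` and `replicate = 0`.
#' @export
average_replicates <- function(series_list) {
  if (inherits(series_list, "hourly_series")) series_list <- list(series_list)
  if (!length(series_list)) stop("empty input")
  n <- vapply(series_list, nrow, integer(1))
  if (length(unique(n)) != 1) stop("alignment error: replicates of unequal length")
  t0 <- series_list[[1]]$timestamp
  for (s in series_list[-1])
    if (!all(as.numeric(s$timestamp) == as.numeric(t0)))
      stop("alignment error: mismatched timestamp grids")
  out <- series_list[[1]]
  out$rsv <- rowMeans(do.call(cbind, lapply(series_list, `[[`, "rsv")))
  out$replicate <- 0L
  out
}

#' Combine several locations into one analysis series
#'
#' Pools locally-annotated series from multiple locations by pointwise mean on
#' the shared local-clock grid, producing the single per-term series used for
#' fitting ("all states combined"). Input series must already be annotated via
#' [to_local_time()] so that 08:00 means 08:00 local everywhere.
#'
#' @param series_list list of annotated [hourly_series] for one term.
#' @param method pooling method; only `"mean"` is supported.
#' @return one annotated `hourly_series` with `location = "combined"`.
#' @export
combine_locations <- function(series_list, method = c("mean")) {
  method <- match.arg(method)
  if (inherits(series_list, "hourly_series")) series_list <- list(series_list)
  if (!length(series_list)) stop("empty input: no series to combine")
  if (!all(vapply(series_list, function(s) "local_time" %in% names(s), logical(1))))
    stop("combine_locations requires locally annotated series (see to_local_time)")
  term <- unique(vapply(series_list, function(s) s$term[1], character(1)))
  if (length(term) != 1) stop("all series must share one term")
  df <- do.call(rbind, lapply(series_list, function(s)
    data.frame(local_time = s$local_time, rsv = s$rsv)))
  agg <- stats::aggregate(rsv ~ local_time, data = df, FUN = mean)
  agg <- agg[order(agg$local_time), ]
  out <- hourly_series(term, "combined", agg$local_time, agg$rsv,
                       replicate = 0L, allow_gaps = TRUE)
  # the combined grid lives on the naive local clock; annotate it as such
  to_local_time(out, "UTC")
}
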