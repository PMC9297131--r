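#' Format a decimal hour as a 24-h clock string
#'
#' @param hours numeric vector of hours in `[0, 24)`.
#' @return character vector `"hh:mm"`, minutes rounded to the nearest minute.
#' @examples
#' format_clock(c(4.5833, 0, 23.999))
#' @export
format_clock <- function(hours) {
  m <- round(hours * 60) %% 1440
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

#' Parse a 24-h clock string to decimal hours
#'
#' @param x character vector `"hh:mm"` (seconds optional) or numeric (returned
#'   as-is modulo 24).
#' @return numeric hours in `[0, 24)`.
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) return(x %% 24)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (any(is.na(p)) || length(p) < 2) stop("invalid clock time", call. = FALSE)
    (p[1] + p[2] / 60 + if (length(p) > 2) p[3] / 3600 else 0) %% 24
  }, numeric(1))
}

#' Shorter-arc circular difference between two clock times
#'
#' @param h1,h2 hours in `[0, 24)` (numeric or `"hh:mm"`).
#' @return absolute difference in hours along the shorter arc, in `[0, 12]`.
#' @export
circ_diff_hours <- function(h1, h2) {
  d <- abs(parse_clock(h1) - parse_clock(h2)) %% 24
  pmin(d, 24 - d)
}

# Deterministic sub-seed derivation: one user-facing seed fans out to the
# simulation, CV-fold and bootstrap RNG streams without collisions.
# Kept strictly below 2^31 - 1 so set.seed() always accepts it.
derive_seed <- function(seed, stream, rep = 0L) {
  offs <- c(sim = 11L, cv = 211L, boot = 3011L, fold = 40009L, misc = 500009L)
  off <- offs[[match.arg(stream, names(offs))]]
  as.integer((as.double(seed) %% 65011) * 32749 + off + 7919 * (as.double(rep) %% 60013)) %% 2147483563L
}

# Evaluate a function under a temporary RNG state so library code does not
# disturb the caller's random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Meteorological season (DJF/MAM/JJA/SON) from a local month number.
season_of_month <- function(month) {
  s <- c("winter", "winter", "spring", "spring", "spring", "summer",
         "summer", "summer", "fall", "fall", "fall", "winter")
  factor(s[month], levels = c("winter", "spring", "summer", "fall"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
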