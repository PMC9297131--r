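#' Hourly means of a series by plotting group
#'
#' Means of the (filtered) series by local hour of day, within each group of
#' the requested family: `"overall"` (one 24-vector), `"day_of_week"` (seven),
#' or `"season_daytype"` (season x weekday/weekend).
#'
#' @param series annotated [hourly_series].
#' @param grouping grouping family.
#' @param values numeric vector to average (default the series `rsv`; pass
#'   [filter_series()] output to plot the outlier-filtered data).
#' @return tibble with columns `group`, `hour_of_day`, `mean_rsv` (24 rows per
#'   group); groups with no observations are dropped with a warning.
#' @export
hourly_means <- function(series,
                         grouping = c("overall", "day_of_week", "season_daytype"),
                         values = series$rsv) {
  grouping <- match.arg(grouping)
  stopifnot("hour_of_day" %in% names(series), length(values) == nrow(series))
  g <- switch(grouping,
    overall = rep("all", nrow(series)),
    day_of_week = c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")[series$day_of_week + 1],
    season_daytype = paste(series$season,
                           ifelse(series$is_weekend, "weekend", "weekday"), sep = "_"))
  df <- tibble::tibble(group = g, hour_of_day = series$hour_of_day, v = values)
  out <- dplyr::summarise(dplyr::group_by(df, .data$group, .data$hour_of_day),
                          mean_rsv = mean(.data$v), n = dplyr::n(), .groups = "drop")
  short <- dplyr::count(out, .data$group)
  if (any(short$n < 24))
    warning("missing panel: group(s) without all 24 hours: ",
            paste(short$group[short$n < 24], collapse = ", "))
  out
}

#' Assemble a normalized polar-plot panel
#'
#' Applies [polar_normalize()] within each group of an [hourly_means()] table
#' so every group's quietest hour maps to radius 1.0.
#'
#' @param means tibble from [hourly_means()].
#' @param term label for the panel title.
#' @param grouping grouping family used (stored for styling).
#' @return tibble of class `polar_panel` with column `radius` added.
#' @export
polar_panel <- function(means, term = "series",
                        grouping = c("overall", "day_of_week", "season_daytype")) {
  grouping <- match.arg(grouping)
  out <- dplyr::mutate(dplyr::group_by(means, .data$group),
                       radius = polar_normalize(.data$mean_rsv))
  out <- dplyr::ungroup(out)
  class(out) <- c("polar_panel", class(out))
  attr(out, "term") <- term
  attr(out, "grouping") <- grouping
  out
}

#' Render a 24-hour polar plot
#'
#' Normalized hourly profiles on polar axes with midnight at the top and
#' hours advancing clockwise. For the season-by-day-type family, weekdays are
#' drawn solid and weekend days dashed, seasons by color.
#'
#' @param panel a [polar_panel()].
#' @param file optional output path (`.png` or `.pdf`); rendered at fixed
#'   size/resolution so identical panels give identical files.
#' @param width,height,dpi device settings for `file` output.
#' @return the ggplot object, invisibly if written to `file`.
#' @export
render_polar <- function(panel, file = NULL, width = 5, height = 5, dpi = 150) {
  stopifnot(inherits(panel, "polar_panel"))
  grouping <- attr(panel, "grouping")
  closed <- dplyr::bind_rows(panel,
                             dplyr::mutate(dplyr::filter(panel, .data$hour_of_day == 0),
                                           hour_of_day = 24))
  if (grouping == "season_daytype") {
    parts <- do.call(rbind, strsplit(closed$group, "_"))
    closed$season <- parts[, 1]
    closed$daytype <- parts[, 2]
    p <- ggplot2::ggplot(closed, ggplot2::aes(.data$hour_of_day, .data$radius,
                                              colour = .data$season,
                                              linetype = .data$daytype,
                                              group = .data$group)) +
      ggplot2::scale_linetype_manual(values = c(weekday = "solid", weekend = "dashed"))
  } else {
    p <- ggplot2::ggplot(closed, ggplot2::aes(.data$hour_of_day, .data$radius,
                                              colour = .data$group,
                                              group = .data$group))
  }
  p <- p + ggplot2::geom_path() +
    ggplot2::coord_polar(theta = "x", start = 0, direction = 1) +
    ggplot2::scale_x_continuous(breaks = seq(0, 21, 3), limits = c(0, 24),
                                labels = sprintf("%02d:00", seq(0, 21, 3))) +
    ggplot2::labs(title = attr(panel, "term"), x = NULL, y = "relative interest") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height, dpi = dpi)
    return(invisible(p))
  }
  p
}
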