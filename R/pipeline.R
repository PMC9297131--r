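#' End-to-end run configuration
#'
#' One configuration object drives the whole pipeline; its single `seed` fans
#' out deterministically to the simulation, CV-fold and bootstrap streams, so
#' a config fully determines every output table.
#'
#' @param csv path to a long-format RSV CSV (see [read_series()]); give this
#'   or `scenario`.
#' @param scenario a [synthetic_spec()] to simulate instead of reading a file.
#' @param terms terms to analyze (CSV input only; default: all terms found).
#' @param timezone_map named character vector `location -> IANA zone` used to
#'   localize CSV input (e.g. `c(NY = "America/New_York")`).
#' @param widths nuisance width preset name or integer vector
#'   (see [width_presets]).
#' @param cv_folds,rule,fold_scheme LASSO selection settings
#'   (see [select_nuisance()]).
#' @param bootstrap a [bootstrap_config()]; its seed is derived from `seed`.
#' @param threshold significance threshold for the diurnality P values
#'   (default 0.001).
#' @param seed master integer seed.
#' @param out_dir output directory (created); `NULL` for no file output.
#' @param figures figure families to render: subset of
#'   `c("overall", "day_of_week", "season_daytype")`, or `NULL` for none.
#' @param detrend_plots plot the filtered-and-detrended series (default) or
#'   only the outlier-filtered one.
#' @return object of class `run_config`.
#' @export
run_config <- function(csv = NULL, scenario = NULL, terms = NULL,
                       timezone_map = NULL, widths = "default",
                       cv_folds = 10, rule = "1se", fold_scheme = "random",
                       bootstrap = bootstrap_config(), threshold = 0.001,
                       seed = 1L, out_dir = NULL, figures = NULL,
                       detrend_plots = TRUE) {
  if (is.null(csv) == is.null(scenario))
    stop("validation error: give exactly one of csv or scenario")
  if (!is.null(csv) && !file.exists(csv))
    stop("validation error: input file does not exist: ", csv)
  if (threshold <= 0 || threshold >= 1)
    stop("validation error: threshold must be in (0, 1)")
  if (!is.null(terms) && !length(terms))
    stop("validation error: empty term list")
  structure(list(csv = csv, scenario = scenario, terms = terms,
                 timezone_map = timezone_map, widths = widths,
                 cv_folds = cv_folds, rule = rule, fold_scheme = fold_scheme,
                 bootstrap = bootstrap, threshold = threshold,
                 seed = as.integer(seed), out_dir = out_dir,
                 figures = figures, detrend_plots = detrend_plots),
            class = "run_config")
}

# Assemble the per-term combined analysis series from a config.
load_input_series <- function(config) {
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    sc$seed <- derive_seed(config$seed, "sim", sc$seed)
    sim <- simulate_series(sc)
    return(setNames(list(list(series = sim$series, truth = sim$truth)), sc$term))
  }
  all <- read_series(config$csv)
  meta <- do.call(rbind, lapply(all, function(s)
    data.frame(term = s$term[1], location = s$location[1])))
  terms <- config$terms %||% unique(meta$term)
  missing_terms <- setdiff(terms, meta$term)
  if (length(missing_terms))
    stop("validation error: term(s) not in input: ", paste(missing_terms, collapse = ", "))
  out <- lapply(terms, function(tm) {
    keep <- which(meta$term == tm)
    by_loc <- split(all[keep], meta$location[keep])
    localized <- lapply(names(by_loc), function(loc) {
      zone <- config$timezone_map[[loc]] %||% "UTC"
      to_local_time(average_replicates(by_loc[[loc]]), zone)
    })
    list(series = combine_locations(localized), truth = NULL)
  })
  setNames(out, terms)
}

#' Run the full diurnal-rhythm analysis
#'
#' Loads or simulates the hourly series, selects nuisance terms by
#' cross-validated LASSO, fits the harmonic regression by OLS, computes the
#' circular summaries with block-bootstrap CIs and P values, and (optionally)
#' writes a per-term summary table (CSV), polar figures, a machine-readable run
#' manifest and a stage log.
#'
#' @param config a [run_config()].
#' @return list: `summary` (one `diurnal_summary` row per term with
#'   significance flags), `models`, `truth` (per-term ground truth for
#'   synthetic input), `log`, and `paths` of any files written. Invisible.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_all <- proc.time()[3]
  log <- character(0)
  stage <- function(name, rows, t0)
    sprintf("stage=%s rows=%d elapsed=%.2fs", name, rows, proc.time()[3] - t0)

  t0 <- proc.time()[3]
  inputs <- load_input_series(config)
  log <- c(log, stage("load", sum(vapply(inputs, function(x) nrow(x$series), integer(1))), t0))

  boot <- config$bootstrap
  boot$seed <- derive_seed(config$seed, "boot")
  models <- list(); rows <- list(); truths <- list()
  for (tm in names(inputs)) {
    s <- inputs[[tm]]$series
    t0 <- proc.time()[3]
    design <- build_design(s, config$widths)
    model <- fit_series(s$rsv, design, cv_folds = config$cv_folds,
                        seed = derive_seed(config$seed, "cv"),
                        rule = config$rule, fold_scheme = config$fold_scheme)
    log <- c(log, stage(paste0("fit:", tm), design$n, t0))
    t0 <- proc.time()[3]
    sm <- bootstrap_summaries(model, boot, term = tm)
    sm$sig_weekday <- sm$p_weekday < config$threshold
    sm$sig_weekend <- sm$p_weekend < config$threshold
    log <- c(log, stage(paste0("bootstrap:", tm), boot$n_reps, t0))
    models[[tm]] <- model
    rows[[tm]] <- sm
    truths[[tm]] <- inputs[[tm]]$truth
  }
  summary <- dplyr::bind_rows(rows)
  class(summary) <- c("diurnal_summary", class(summary))

  paths <- list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$summary <- file.path(config$out_dir, "summary.csv")
    write_summary_table(summary, paths$summary)
    paths$manifest <- file.path(config$out_dir, "manifest.json")
    write_manifest(config, paths$manifest)
    if (!is.null(config$figures)) {
      for (tm in names(inputs)) {
        s <- inputs[[tm]]$series
        vals <- filter_series(models[[tm]], detrend = config$detrend_plots)
        if (config$detrend_plots) vals <- vals - mean(vals) + mean(filter_series(models[[tm]]))
        for (grp in config$figures) {
          t0 <- proc.time()[3]
          f <- file.path(config$out_dir, sprintf("polar_%s_%s.png", gsub("\\W+", "_", tm), grp))
          render_polar(polar_panel(hourly_means(s, grp, vals), term = tm, grouping = grp),
                       file = f)
          paths$figures <- c(paths$figures, f)
          log <- c(log, stage(paste0("plot:", tm, ":", grp), 24L, t0))
        }
      }
    }
    paths$log <- file.path(config$out_dir, "run.log")
    writeLines(c(log, sprintf("stage=total rows=%d elapsed=%.2fs",
                              nrow(summary), proc.time()[3] - t_all)), paths$log)
  }
  invisible(list(summary = summary, models = models, truth = truths,
                 log = log, paths = paths))
}

#' Nuisance-width sensitivity analysis
#'
#' Reruns selection + OLS + point summaries under two or more width presets on
#' the same input series and tabulates pairwise differences: circular median
#' shifts in minutes and amplitude-to-mean-ratio differences.
#'
#' @param config a [run_config()].
#' @param presets character vector (>= 2) of [width_presets] names, or a named
#'   list of integer width sets.
#' @return list: `summaries` (per preset x term point estimates) and
#'   `comparison` (pairwise differences).
#' @export
run_sensitivity <- function(config, presets = names(width_presets)) {
  stopifnot(inherits(config, "run_config"))
  if (length(presets) < 2) stop("need at least two width presets")
  if (is.character(presets)) presets <- setNames(lapply(presets, identity), presets)
  inputs <- load_input_series(config)
  rows <- list()
  for (tm in names(inputs)) {
    s <- inputs[[tm]]$series
    for (pn in names(presets)) {
      design <- build_design(s, presets[[pn]])
      model <- fit_series(s$rsv, design, cv_folds = config$cv_folds,
                          seed = derive_seed(config$seed, "cv"),
                          rule = config$rule, fold_scheme = config$fold_scheme)
      rows[[paste(tm, pn)]] <- tibble::tibble(
        term = tm, preset = pn,
        median_weekday = circular_median_time(diurnal_curve(model, "weekday")),
        median_weekend = circular_median_time(diurnal_curve(model, "weekend")),
        amr_weekday = amplitude_mean_ratio(diurnal_curve(model, "weekday")),
        amr_weekend = amplitude_mean_ratio(diurnal_curve(model, "weekend")),
        amr_contrast = amr_contrast(model),
        n_selected = nrow(model$selected))
    }
  }
  summaries <- dplyr::bind_rows(rows)
  cmp <- list()
  pn <- names(presets)
  for (tm in unique(summaries$term)) {
    st <- summaries[summaries$term == tm, ]
    for (i in seq_along(pn)) for (j in seq_along(pn)) if (i < j) {
      a <- st[st$preset == pn[i], ]; b <- st[st$preset == pn[j], ]
      cmp[[paste(tm, i, j)]] <- tibble::tibble(
        term = tm, preset_a = pn[i], preset_b = pn[j],
        dmedian_weekday_min = 60 * circ_diff_hours(a$median_weekday, b$median_weekday),
        dmedian_weekend_min = 60 * circ_diff_hours(a$median_weekend, b$median_weekend),
        damr_weekday = abs(a$amr_weekday - b$amr_weekday),
        damr_weekend = abs(a$amr_weekend - b$amr_weekend),
        damr_contrast = abs(a$amr_contrast - b$amr_contrast))
    }
  }
  list(summaries = summaries, comparison = dplyr::bind_rows(cmp))
}

#' Write the per-term summary table as CSV
#'
#' Clock statistics are formatted `hh:mm`; ratios and P values are written at
#' fixed precision so identical runs produce byte-identical files.
#'
#' @param summary a `diurnal_summary` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summary, path) {
  df <- as.data.frame(summary)
  clock_cols <- grep("^median_week(day|end)(_lo|_hi)?$", names(df), value = TRUE)
  for (cc in clock_cols) df[[cc]] <- format_clock(df[[cc]])
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Machine-readable manifest: everything needed to reproduce the tables.
write_manifest <- function(config, path) {
  sc <- config$scenario
  jsonlite::write_json(list(
    package = "searchcycles",
    version = as.character(utils::packageVersion("searchcycles")),
    seed = config$seed,
    input = if (is.null(sc)) list(csv = config$csv, terms = config$terms,
                                  timezone_map = as.list(config$timezone_map %||% list()))
            else list(scenario = unclass(sc)[setdiff(names(sc), "harmonics")],
                      harmonics = lapply(sc$harmonics, function(h) as.list(h %||% list()))),
    widths = if (is.character(config$widths)) config$widths else as.integer(config$widths),
    cv = list(folds = config$cv_folds, rule = config$rule,
              fold_scheme = config$fold_scheme),
    bootstrap = unclass(config$bootstrap),
    threshold = config$threshold), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
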