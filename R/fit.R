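#' Select outlier-indicator terms by cross-validated LASSO
#'
#' Runs a LASSO in which only the nuisance indicator columns are penalized:
#' the intercept, trend polynomials and diurnal harmonics always stay in the
#' model, so shrinkage cannot bias the coefficients the circular summaries are
#' built from. Nuisance columns are standardized to unit Euclidean norm inside
#' the LASSO only (wide windows would otherwise be under-penalized). The
#' penalty is chosen by K-fold cross-validation; the default `"1se"` rule takes
#' the sparsest penalty within one standard error of the CV minimum, keeping
#' the number of selected terms small.
#'
#' Folds are assigned at random by default. A localized indicator column is
#' nonzero only on one short stretch of the series, so with contiguous fold
#' blocks the entire support of a true outlier column can fall in the held-out
#' fold, making the column all-zero in training and invisible to CV; random
#' assignment spreads its support across folds and restores selection power.
#' `fold_scheme = "contiguous"` is available for strongly autocorrelated noise.
#'
#' @param y numeric response (RSV) on the design's rows.
#' @param design a [build_design()] object.
#' @param cv_folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param rule penalty rule: `"1se"` (default) or `"min"`.
#' @param fold_scheme `"random"` (default) or `"contiguous"`.
#' @param ... further arguments to [glmnet::cv.glmnet()] (e.g. `nlambda`).
#' @return list with `selected` (data frame `col, width, m` of nonzero
#'   indicator columns, ordered narrow-first then earliest) and `cv_details`.
#' @export
select_nuisance <- function(y, design, cv_folds = 10, seed = 1L,
                            rule = c("1se", "min"),
                            fold_scheme = c("random", "contiguous"), ...) {
  rule <- match.arg(rule)
  fold_scheme <- match.arg(fold_scheme)
  stopifnot(inherits(design, "design_matrices"), length(y) == design$n)
  p_un <- ncol(design$trend) + ncol(design$harmonic)
  if (length(y) < p_un + 1) stop("rank error: fewer rows than unpenalized columns")
  norms <- sqrt(Matrix::colSums(design$nuisance^2))
  norms[norms == 0] <- 1
  Ns <- design$nuisance %*% Matrix::Diagonal(x = 1 / norms)
  X <- cbind2(Matrix::Matrix(cbind(design$trend, design$harmonic), sparse = TRUE), Ns)
  pf <- c(rep(0, p_un), rep(1, ncol(Ns)))
  n <- length(y)
  foldid <- if (fold_scheme == "random")
    with_seed(derive_seed(seed, "fold"), sample(rep(seq_len(cv_folds), length.out = n)))
  else rep(seq_len(cv_folds), each = ceiling(n / cv_folds))[seq_len(n)]
  cv <- glmnet::cv.glmnet(X, y, foldid = foldid, penalty.factor = pf,
                          standardize = FALSE, intercept = TRUE, ...)
  lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  beta <- as.numeric(stats::coef(cv, s = lam))[-1]
  nz <- which(beta[p_un + seq_len(ncol(Ns))] != 0)
  sel <- design$nuisance_meta[nz, , drop = FALSE]
  sel <- sel[order(sel$width, sel$m), , drop = FALSE]
  list(selected = sel,
       cv_details = list(folds = cv_folds, fold_scheme = fold_scheme,
                         rule = rule, lambda = lam,
                         lambda_range = range(cv$lambda), seed = seed))
}

#' Fit the harmonic regression by ordinary least squares
#'
#' Exact least-squares fit of intercept + orthogonal cubic trend + day-type
#' harmonics + weekend level + the selected nuisance indicator columns.
#' Exactly collinear selected columns are dropped with a warning, keeping the
#' narrowest width and then the earliest window (the most local outlier
#' explanation). The returned model carries the residuals, the
#' outlier-filtered series (observed minus the fitted nuisance contribution)
#' and everything needed to evaluate diurnal curves and to bootstrap.
#'
#' @param y numeric response on the design's rows.
#' @param design a [build_design()] object.
#' @param selected data frame of selected nuisance columns (`col, width, m`),
#'   e.g. `select_nuisance(...)$selected`; may be empty.
#' @param cv_details optional selection metadata stored on the model.
#' @return object of class `serfling_fit`.
#' @export
fit_ols <- function(y, design, selected = NULL, cv_details = NULL) {
  stopifnot(inherits(design, "design_matrices"), length(y) == design$n)
  if (is.null(selected)) selected <- design$nuisance_meta[0, ]
  selected <- selected[order(selected$width, selected$m), , drop = FALSE]
  Nsel <- as.matrix(design$nuisance[, selected$col, drop = FALSE])
  X <- cbind(`(Intercept)` = 1, design$trend, design$harmonic, Nsel)
  fit <- stats::lm.fit(X, y)
  if (anyNA(fit$coefficients)) {
    drop <- names(fit$coefficients)[is.na(fit$coefficients)]
    if (any(!drop %in% selected$col))
      stop("rank error: unpenalized design block is rank deficient")
    warning("dropping collinear nuisance column(s): ", paste(drop, collapse = ", "))
    selected <- selected[!selected$col %in% drop, , drop = FALSE]
    Nsel <- as.matrix(design$nuisance[, selected$col, drop = FALSE])
    X <- cbind(`(Intercept)` = 1, design$trend, design$harmonic, Nsel)
    fit <- stats::lm.fit(X, y)
  }
  b <- fit$coefficients
  hm <- design$harmonic_meta
  harm_names <- hm$col
  nuis_coef <- b[selected$col]
  nuis_contrib <- if (length(nuis_coef)) as.numeric(Nsel %*% nuis_coef) else numeric(design$n)
  fitted <- as.numeric(X %*% b)
  structure(list(
    intercept = unname(b["(Intercept)"]),
    trend_coeffs = b[paste0("trend", 1:3)],
    harmonic_coeffs = b[harm_names],
    weekend_level = unname(b["weekend_level"]),
    nuisance_coeffs = data.frame(selected, coef = unname(nuis_coef),
                                 row.names = NULL),
    selected = selected,
    residuals = y - fitted,
    fitted = fitted,
    fitted_clean = fitted - nuis_contrib,
    filtered_series = y - nuis_contrib,
    observed = y,
    qr = fit$qr,
    coef_names = names(b),
    design = design,
    cv_details = cv_details), class = "serfling_fit")
}

#' One-call nuisance selection plus OLS fit
#'
#' @inheritParams select_nuisance
#' @return a `serfling_fit` (see [fit_ols()]).
#' @export
fit_series <- function(y, design, cv_folds = 10, seed = 1L,
                       rule = c("1se", "min"),
                       fold_scheme = c("random", "contiguous"), ...) {
  sel <- select_nuisance(y, design, cv_folds = cv_folds, seed = seed,
                         rule = rule, fold_scheme = fold_scheme, ...)
  fit_ols(y, design, sel$selected, cv_details = sel$cv_details)
}

#' Outlier-filtered series of a fitted model
#'
#' The observed series minus the fitted contribution of the selected nuisance
#' indicator columns; trend and diurnal harmonics are retained. With an empty
#' selection this is the observed series unchanged.
#'
#' @param model a `serfling_fit`.
#' @param detrend additionally remove the fitted trend polynomial (the mean
#'   level is kept), as used for visualisation.
#' @return numeric vector, same length as the observed series.
#' @export
filter_series <- function(model, detrend = FALSE) {
  out <- model$filtered_series
  if (detrend) {
    tr <- as.numeric(model$design$trend %*% model$trend_coeffs)
    out <- out - tr
  }
  out
}

#' @export
print.serfling_fit <- function(x, ...) {
  cat("Serfling harmonic fit: n =", x$design$n, "\n")
  cat("  intercept", format(x$intercept, digits = 5),
      "| weekend level", format(x$weekend_level, digits = 4), "\n")
  cat("  selected nuisance terms:", nrow(x$selected), "\n")
  invisible(x)
}

#' Serialize a fitted model to a flat coefficient table
#'
#' @param model a `serfling_fit`.
#' @param path optional CSV path; if given the table is written there.
#' @return tibble with columns `block, col, width, m, daytype, n, fn, coef`.
#' @export
coef_table <- function(model, path = NULL) {
  hm <- model$design$harmonic_meta
  tab <- dplyr::bind_rows(
    tibble::tibble(block = "intercept", col = "(Intercept)",
                   coef = model$intercept),
    tibble::tibble(block = "trend", col = paste0("trend", 1:3),
                   coef = unname(model$trend_coeffs)),
    tibble::tibble(block = "harmonic", col = hm$col, daytype = hm$daytype,
                   n = hm$n, fn = hm$fn,
                   coef = unname(model$harmonic_coeffs[hm$col])),
    tibble::tibble(block = "weekend_level", col = "weekend_level",
                   coef = model$weekend_level),
    if (nrow(model$nuisance_coeffs))
      tibble::tibble(block = "nuisance", col = model$nuisance_coeffs$col,
                     width = model$nuisance_coeffs$width,
                     m = model$nuisance_coeffs$m,
                     coef = model$nuisance_coeffs$coef)
  )
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}
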