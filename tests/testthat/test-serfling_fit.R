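# Unit-scale fixtures use 8 weeks of hourly data so each CV fit stays cheap.

test_that("clean harmonic signal selects no (or almost no) nuisance terms", {
  spurious <- 0
  for (seed in 1:8) {
    sim <- simulate_series(demo_spec(seed = seed))
    design <- build_design(sim$series)
    sel <- select_nuisance(sim$series$rsv, design, seed = seed, nlambda = 40)
    spurious <- spurious + nrow(sel$selected)
  }
  expect_lte(spurious, 1)
})

test_that("an aligned boxcar surge selects exactly its covering indicator", {
  sim <- simulate_series(demo_spec(noise_sd = 2, outliers = list(c(800, 8, 60))))
  design <- build_design(sim$series)
  sel <- select_nuisance(sim$series$rsv, design, seed = 4)
  expect_true("k8_m100" %in% sel$selected$col)
})

test_that("two disjoint surges are both covered by the selection", {
  sim <- simulate_series(demo_spec(noise_sd = 2,
                                   outliers = list(c(400, 8, 50), c(960, 16, 45))))
  design <- build_design(sim$series)
  sel <- select_nuisance(sim$series$rsv, design, seed = 4)
  covered <- Matrix::rowSums(design$nuisance[, sel$selected$col, drop = FALSE]) > 0
  surge_rows <- sim$series$elapsed_hours %in% c(400:407, 960:975)
  expect_true(all(covered[surge_rows]))
})

test_that("OLS recovers noiseless harmonic coefficients exactly", {
  spec <- demo_spec(trend = c(0.05, -3e-4, 2e-6))
  sim <- simulate_series(spec)
  design <- build_design(sim$series)
  model <- fit_ols(sim$series$rsv, design, selected = NULL)
  b <- model$harmonic_coeffs
  # a*cos(n w t - phi) = a*cos(phi)*cos(n w t) + a*sin(phi)*sin(n w t)
  w <- 2 * pi / 24
  expect_equal(unname(b["weekday_cos_1"]), 10 * cos(w * 5), tolerance = 1e-8)
  expect_equal(unname(b["weekday_sin_1"]), 10 * sin(w * 5), tolerance = 1e-8)
  expect_equal(unname(b["weekday_cos_2"]), 3 * cos(2 * w * 2), tolerance = 1e-8)
  expect_equal(unname(b["weekend_cos_1"]), 6 * cos(w * 7), tolerance = 1e-8)
  expect_lt(abs(b["weekday_sin_3"]), 1e-8)
  expect_lt(abs(model$weekend_level), 1e-7)
  expect_lt(max(abs(model$residuals)), 1e-7)
})

test_that("constant input yields intercept-only fit; shifts hit the intercept", {
  s <- to_local_time(mk_series(rep(50, 1344)), "UTC")
  design <- build_design(s)
  m <- fit_ols(s$rsv, design, selected = NULL)
  expect_equal(m$intercept, 50, tolerance = 1e-10)
  expect_lt(max(abs(c(m$trend_coeffs, m$harmonic_coeffs, m$weekend_level))), 1e-10)

  sim <- simulate_series(demo_spec(noise_sd = 3))
  design <- build_design(sim$series)
  m1 <- fit_ols(sim$series$rsv, design, selected = NULL)
  m2 <- fit_ols(sim$series$rsv + 10, design, selected = NULL)
  expect_equal(m2$intercept, m1$intercept + 10, tolerance = 1e-9)
  expect_equal(m2$harmonic_coeffs, m1$harmonic_coeffs, tolerance = 1e-9)
  expect_equal(m2$trend_coeffs, m1$trend_coeffs, tolerance = 1e-9)
})

test_that("residuals are orthogonal to every included column", {
  sim <- simulate_series(demo_spec(noise_sd = 5, outliers = list(c(800, 8, 60))))
  design <- build_design(sim$series)
  model <- fit_series(sim$series$rsv, design, seed = 2)
  X <- cbind(1, design$trend, design$harmonic,
             as.matrix(design$nuisance[, model$selected$col, drop = FALSE]))
  Xs <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  expect_lt(max(abs(crossprod(Xs, model$residuals))), 1e-6)
})

test_that("filtering removes the surge and is idempotent", {
  clean <- simulate_series(demo_spec(seed = 3))
  noisy <- simulate_series(demo_spec(noise_sd = 3, seed = 3,
                                     outliers = list(c(800, 8, 60))))
  design <- build_design(noisy$series)
  model <- fit_series(noisy$series$rsv, design, seed = 5)
  expect_true("k8_m100" %in% model$selected$col)
  f <- filter_series(model)
  win <- noisy$series$elapsed_hours %in% 800:807
  expect_lt(mean(abs(f[win] - clean$series$rsv[win])), 3)
  expect_lt(max(abs(f[win] - clean$series$rsv[win])), 9)

  # no selection -> identity
  m0 <- fit_ols(noisy$series$rsv, design, selected = NULL)
  expect_identical(filter_series(m0), noisy$series$rsv)

  # noiseless surge: filtering then re-selecting finds nothing further
  pure <- simulate_series(demo_spec(outliers = list(c(800, 8, 60))))
  dsg <- build_design(pure$series)
  m <- fit_series(pure$series$rsv, dsg, seed = 6)
  resel <- select_nuisance(filter_series(m), dsg, seed = 7)
  expect_equal(nrow(resel$selected), 0)
})

test_that("exactly collinear selections drop the widest column with a warning", {
  s <- to_local_time(mk_series(50 + rep(rep(c(0, 5), each = 8), length.out = 672)), "UTC")
  design <- build_design(s, widths = c(8, 16))
  sel <- design$nuisance_meta[design$nuisance_meta$col %in%
                                c("k8_m0", "k8_m1", "k16_m0"), ]
  expect_warning(m <- fit_ols(s$rsv, design, selected = sel), "k16_m0")
  expect_setequal(m$selected$col, c("k8_m0", "k8_m1"))
})

test_that("LASSO-then-OLS matches exhaustive best-subset on a strong surge", {
  spec <- synthetic_spec(n_hours = 480, baseline = 50,
                         harmonics = list(weekday = harmonic_set(1, 8, peak_hour = 6),
                                          weekend = harmonic_set(1, 8, peak_hour = 6)),
                         noise_sd = 2, outliers = list(c(96, 16, 40)), seed = 11)
  sim <- simulate_series(spec)
  design <- build_design(sim$series, widths = 16)   # 30 candidate columns
  model <- fit_series(sim$series$rsv, design, seed = 12)
  expect_identical(model$selected$col, "k16_m6")

  # oracle: best single-column OLS by residual sum of squares
  rss <- vapply(design$nuisance_meta$col, function(cc) {
    X <- cbind(1, design$trend, design$harmonic,
               as.matrix(design$nuisance[, cc, drop = FALSE]))
    sum(lm.fit(X, sim$series$rsv)$residuals^2)
  }, numeric(1))
  expect_identical(unname(design$nuisance_meta$col[which.min(rss)]), "k16_m6")
  oracle <- fit_ols(sim$series$rsv, design,
                    design$nuisance_meta[design$nuisance_meta$col == "k16_m6", ])
  expect_equal(model$harmonic_coeffs, oracle$harmonic_coeffs, tolerance = 1e-10)
})

test_that("filtering moves amplitude estimates toward the truth", {
  # surge aligned with the k=8 window grid, the shape the indicators absorb
  better <- 0
  for (seed in 1:10) {
    sim <- simulate_series(demo_spec(noise_sd = 5, seed = seed,
                                     outliers = list(c(800, 8, 60))))
    design <- build_design(sim$series)
    truth <- sim$truth
    unf <- fit_ols(sim$series$rsv, design, selected = NULL)
    fit <- fit_series(sim$series$rsv, design, seed = seed, nlambda = 40)
    err <- function(m) abs(amplitude_mean_ratio(diurnal_curve(m, "weekday")) - truth$amr_weekday) +
      abs(amplitude_mean_ratio(diurnal_curve(m, "weekend")) - truth$amr_weekend)
    if (err(fit) <= err(unf)) better <- better + 1
  }
  expect_gte(better, 8)
})
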