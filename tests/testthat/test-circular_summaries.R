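w24 <- 2 * pi / 24

test_that("diurnal curves evaluate the intercept + harmonics in closed form", {
  m <- fake_model(intercept = 50)
  expect_equal(diurnal_curve(m, "weekday")$values, rep(50, 1440))

  m <- fake_model(intercept = 10, coefs = c(weekday_cos_1 = 3))
  cv <- diurnal_curve(m, "weekday")
  expect_equal(max(cv$values), 13, tolerance = 1e-12)
  expect_equal(cv$grid[which.max(cv$values)], 0)
  expect_equal(cv$values, 10 + 3 * cos(w24 * cv$grid), tolerance = 1e-12)

  # weekend curve with identical harmonics and a +5 level is weekday + 5
  m <- fake_model(intercept = 10,
                  coefs = c(weekday_cos_1 = 3, weekend_cos_1 = 3),
                  weekend_level = 5)
  expect_equal(diurnal_curve(m, "weekend")$values,
               diurnal_curve(m, "weekday")$values + 5, tolerance = 1e-12)
})

test_that("amplitude-to-mean ratio matches closed forms and brute force", {
  g <- seq(0, 24 - 1 / 60, by = 1 / 60)
  expect_equal(amplitude_mean_ratio(make_curve(10 + 3 * cos(w24 * g))), 0.6,
               tolerance = 1e-9)
  expect_equal(amplitude_mean_ratio(make_curve(rep(5, 1440))), 0)
  expect_error(amplitude_mean_ratio(make_curve(rep(-1, 1440))), "mean")

  f <- function(t) 10 + 3 * cos(w24 * t) + 1 * cos(2 * w24 * t)
  coarse <- amplitude_mean_ratio(make_curve(f(g), g))
  g2 <- seq(0, 24 - 1 / 120, by = 1 / 120)
  fine <- amplitude_mean_ratio(make_curve(f(g2), g2))
  expect_lt(abs(coarse - fine), 1e-6)

  # invariant to time shifts, scale-invariant
  expect_equal(amplitude_mean_ratio(make_curve(f(g + 4.25))), coarse, tolerance = 1e-6)
  expect_equal(amplitude_mean_ratio(make_curve(3 * f(g))), coarse, tolerance = 1e-12)
})

test_that("circular median finds the peak of unimodal curves", {
  g <- seq(0, 24 - 1 / 60, by = 1 / 60)
  cv <- make_curve(10 + 3 * cos(w24 * (g - 5)))
  expect_equal(circular_median_time(cv), 5, tolerance = 1 / 60 + 1e-9)
  # shift equivariance (mod 24)
  for (delta in c(3, 11.5, 20)) {
    shifted <- make_curve(10 + 3 * cos(w24 * (g - 5 - delta)))
    expect_equal(circular_median_time(shifted), (5 + delta) %% 24,
                 tolerance = 1 / 60 + 1e-9)
  }
  expect_error(circular_median_time(make_curve(rep(4, 1440))), "constant")
})

test_that("circular median agrees with the exhaustive-search oracle", {
  # bimodal: von-Mises-like bumps at 04:00 (heavy) and 16:00 (light)
  g <- seq(0, 24 - 0.1, by = 0.1)
  v <- 3 * exp(cos(w24 * (g - 4))) + 1 * exp(cos(w24 * (g - 16)))
  got <- circular_median_time(make_curve(v, g))
  want <- brute_circ_median(g, v - min(v))
  expect_equal(got, want, tolerance = 1e-9)

  # randomized multimodal curves, coarse grid for oracle speed
  set.seed(31)
  for (i in 1:25) {
    co <- rnorm(8)
    v <- numeric(length(g)) + 10
    for (k in 1:4) v <- v + co[2 * k - 1] * sin(k * w24 * g) + co[2 * k] * cos(k * w24 * g)
    v <- v - min(v) + 0.5
    expect_equal(circular_median_time(make_curve(v, g)),
                 brute_circ_median(g, v - min(v)), tolerance = 0.1 + 1e-9)
  }
})

test_that("amr contrast uses the average-of-means denominator and its sign", {
  m <- fake_model(intercept = 10,
                  coefs = c(weekday_cos_1 = 3, weekend_cos_1 = 3))
  expect_equal(amr_contrast(m), 0, tolerance = 1e-12)

  m <- fake_model(intercept = 10,
                  coefs = c(weekday_cos_1 = 3, weekend_cos_1 = 1))
  expect_equal(amr_contrast(m), (2 - 6) / 10, tolerance = 1e-9)

  m2 <- fake_model(intercept = 20,
                   coefs = c(weekday_cos_1 = 6, weekend_cos_1 = 2))
  expect_equal(amr_contrast(m2), amr_contrast(m), tolerance = 1e-9)
})

test_that("peak-time differences are banded on the shorter arc", {
  expect_identical(median_diff_band("04:35", "05:38"), "0-2")
  # 13:24 vs 00:13: arcs are 13.18 and 10.82 h; the shorter is 10.82
  expect_identical(median_diff_band("13:24", "00:13"), "10-12")
  expect_identical(median_diff_band("08:00", "08:00"), "0-2")
  expect_equal(circ_diff_hours("13:24", "00:13"), 10.8167, tolerance = 1e-4)
})

test_that("polar normalization maps the quietest hour to exactly 1", {
  expect_equal(polar_normalize(c(2, 4, 8)), c(1, 2, 4))
  expect_equal(polar_normalize(rep(7, 24)), rep(1, 24))
  set.seed(2)
  x <- runif(24, 1, 99)
  expect_equal(min(polar_normalize(x)), 1)
  expect_error(polar_normalize(c(0, 1)), "positive")
})

test_that("clock formatting round-trips", {
  expect_identical(format_clock(c(4 + 35 / 60, 0, 23 + 59 / 60)),
                   c("04:35", "00:00", "23:59"))
  expect_equal(parse_clock(c("04:35", "23:59")), c(4 + 35 / 60, 23 + 59 / 60),
               tolerance = 1e-9)
})
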