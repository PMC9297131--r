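test_that("CSV round-trip preserves values, timestamps and grouping", {
  s1 <- mk_series(c(10, 20, 30), term = "pink eye", loc = "NY")
  s2 <- mk_series(c(5, 6, 7), term = "pink eye", loc = "CA", rep_id = 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(list(s1, s2), path)
  back <- read_series(path)
  expect_length(back, 2)
  got <- back[[which(vapply(back, function(x) x$location[1], "") == "NY")]]
  expect_identical(got$rsv, s1$rsv)
  expect_identical(as.numeric(got$timestamp), as.numeric(s1$timestamp))
  expect_identical(got$term[1], "pink eye")
})

test_that("schema and invariant violations are rejected with row context", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(term = "a", timestamp_utc = "2018-01-01 00:00:00", rsv = 1),
            path, row.names = FALSE)
  expect_error(read_series(path), "schema error")

  s <- mk_series(c(1, 2, 3))
  s$rsv[2] <- -1
  expect_error(validate_hourly_series(s), "negative rsv.*2")
  s <- mk_series(c(1, 2, 3))
  s$timestamp[3] <- s$timestamp[1]
  expect_error(validate_hourly_series(s), "non-monotone")
  expect_error(validate_hourly_series(mk_series(c(50, 120)), raw = TRUE), "raw rsv")
})

test_that("local annotation reflects zone offsets, DST, weekends and seasons", {
  s <- hourly_series("t", "NY", as.POSIXct("2018-01-01 05:00:00", tz = "UTC"), 1)
  a <- to_local_time(s, "America/New_York")
  expect_equal(a$hour_of_day, 0)          # EST, UTC-5
  expect_equal(a$elapsed_hours, 0)        # local midnight Jan 1
  expect_identical(as.character(a$season), "winter")

  s <- hourly_series("t", "NY", as.POSIXct("2018-07-01 04:00:00", tz = "UTC"), 1)
  a <- to_local_time(s, "America/New_York")
  expect_equal(a$hour_of_day, 0)          # EDT, UTC-4
  expect_identical(as.character(a$season), "summer")

  s <- hourly_series("t", "NY", as.POSIXct("2018-01-06 12:00:00", tz = "UTC"), 1)
  a <- to_local_time(s, "America/New_York")
  expect_true(a$is_weekend)               # Jan 6 2018 was a Saturday
  expect_equal(a$day_of_week, 6)

  expect_error(to_local_time(s, "Mars/Olympus"), "unknown time zone")
})

test_that("annotation is a pure, idempotent function of timestamp and zone", {
  s <- mk_series(runif(72, 10, 90))
  a1 <- to_local_time(s, "America/Chicago")
  a2 <- to_local_time(a1, "America/Chicago")
  expect_identical(a1$hour_of_day, a2$hour_of_day)
  expect_identical(a1$elapsed_hours, a2$elapsed_hours)
  expect_identical(a1$is_weekend, a1$day_of_week %in% c(0, 6))
  expect_identical(diff(a1$elapsed_hours), rep(1, 71))
})

test_that("replicate averaging is the pointwise mean with sentinel id", {
  r1 <- mk_series(c(10, 20, 30))
  r2 <- mk_series(c(30, 20, 10), rep_id = 2L)
  avg <- average_replicates(list(r1, r2))
  expect_equal(avg$rsv, c(20, 20, 20))
  expect_equal(avg$replicate, rep(0L, 3))
  expect_equal(average_replicates(list(r1))$rsv, r1$rsv)
  expect_error(average_replicates(list(r1, mk_series(c(1, 2)))), "alignment error")
})

test_that("combining locations pools by mean on the local-clock grid", {
  a <- to_local_time(mk_series(rep(40, 48), loc = "NY"), "UTC")
  b <- to_local_time(mk_series(rep(60, 48), loc = "CA"), "UTC")
  comb <- combine_locations(list(a, b))
  expect_equal(comb$rsv, rep(50, 48))
  expect_equal(combine_locations(list(a))$rsv, a$rsv)
  expect_error(combine_locations(list()), "empty input")
  expect_error(combine_locations(list(mk_series(1:3))), "annotated")
})

test_that("pooling and averaging commute with adding a constant", {
  set.seed(42)
  vals <- runif(48, 20, 80)
  a <- to_local_time(mk_series(vals, loc = "NY"), "UTC")
  b <- to_local_time(mk_series(rev(vals), loc = "CA"), "UTC")
  shift <- function(s, c) { s$rsv <- s$rsv + c; s }
  expect_equal(combine_locations(list(shift(a, 7), shift(b, 7)))$rsv,
               combine_locations(list(a, b))$rsv + 7)
  expect_equal(average_replicates(list(shift(a, 3), shift(b, 3)))$rsv,
               average_replicates(list(a, b))$rsv + 3)
})

test_that("combining 10 locations shrinks independent noise variance ~10-fold", {
  set.seed(7)
  n <- 1500
  signal <- 50 + 10 * cos(2 * pi / 24 * (0:(n - 1)))
  states <- lapply(1:10, function(i)
    to_local_time(mk_series(signal + rnorm(n), loc = sprintf("S%02d", i)), "UTC"))
  comb <- combine_locations(states)
  v_single <- var(states[[1]]$rsv - signal)
  v_comb <- var(comb$rsv - signal)
  expect_gt(v_comb / v_single, 0.05)
  expect_lt(v_comb / v_single, 0.2)
})
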