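test_that("haversine distance matches closed-form values and is symmetric", {
  expect_equal(haversine_km(35, 139, 35, 139), 0)
  expect_equal(haversine_km(0, 0, 1, 0), 111.195, tolerance = 1e-3 / 111.195)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-8)
  set.seed(1)
  for (i in 1:20) {
    a <- c(runif(1, -80, 80), runif(1, -180, 180))
    b <- c(runif(1, -80, 80), runif(1, -180, 180))
    expect_equal(haversine_km(a[1], a[2], b[1], b[2]),
                 haversine_km(b[1], b[2], a[1], a[2]))
    expect_gte(haversine_km(a[1], a[2], b[1], b[2]), 0)
  }
  expect_error(haversine_km(NA, 0, 0, 0), "finite")
  expect_error(haversine_km(95, 0, 0, 0), "latitude")
})

test_that("haversine agrees with geosphere on a common sphere radius", {
  skip_if_not_installed("geosphere")
  set.seed(42)
  p1 <- cbind(runif(50, -180, 180), runif(50, -85, 85))
  p2 <- cbind(runif(50, -180, 180), runif(50, -85, 85))
  ref <- geosphere::distHaversine(p1, p2, r = 6371000) / 1000
  got <- haversine_km(p1[, 2], p1[, 1], p2[, 2], p2[, 1])
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("step series gives expected lengths, speeds and turning angles", {
  # collinear: three equal fixes along one meridian
  fx <- make_fixes(c(0, 10, 20), lat = c(0, 0.01, 0.02), lon = 0)
  st <- track_steps(fx)
  expect_equal(st$step_km[1], st$step_km[2])
  expect_equal(st$turn_rad[2], 0, tolerance = 1e-9)
  expect_true(is.na(st$turn_rad[1]) && is.na(st$turn_rad[3]))
  expect_equal(st$speed_kmh[1], st$step_km[1] / (10 / 60))

  # reversal: east then back west
  fx <- make_fixes(c(0, 10, 20), lat = 0, lon = c(0, 0.009, 0))
  st <- track_steps(fx)
  expect_equal(abs(st$turn_rad[2]), pi, tolerance = 1e-9)

  # right angle: north then east at the equator
  fx <- make_fixes(c(0, 10, 20), lat = c(0, 0.009, 0.009), lon = c(0, 0, 0.009))
  st <- track_steps(fx)
  expect_equal(abs(st$turn_rad[2]), pi / 2, tolerance = 1e-3)
  # north then east is a right (clockwise) turn: negative under the
  # counterclockwise-positive convention
  expect_lt(st$turn_rad[2], 0)

  expect_error(track_steps(make_fixes(0, 0, 0)), "at least 2")
})

test_that("turning angles stay in (-pi, pi] and path length is reversal-invariant", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 12
    fx <- make_fixes(seq(0, by = 10, length.out = n),
                     lat = cumsum(rnorm(n, 0, 0.01)),
                     lon = cumsum(rnorm(n, 0, 0.01)))
    st <- track_steps(fx)
    tr <- st$turn_rad[!is.na(st$turn_rad)]
    expect_true(all(tr > -pi & tr <= pi))
    rev_fx <- fx
    rev_fx$lat <- rev(fx$lat); rev_fx$lon <- rev(fx$lon)
    expect_equal(sum(track_steps(rev_fx)$step_km, na.rm = TRUE),
                 sum(st$step_km, na.rm = TRUE))
  }
})

test_that("speed filter removes spikes by forward sweep against last kept fix", {
  # all slow: untouched
  fx <- make_fixes(c(0, 10, 20), lat = c(0, 0.01, 0.02), lon = 0)
  out <- filter_speed(fx, vmax_kmh = 90)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_removed"), 0)

  # one spike implying ~300 km/h both ways
  fx <- make_fixes(c(0, 10, 20), lat = c(0, 0.45, 0.02), lon = 0)
  out <- filter_speed(fx, vmax_kmh = 90)
  expect_equal(nrow(out), 2)
  expect_equal(out$lat, c(0, 0.02))

  # alternating 80 / 95 km/h from each kept predecessor: hand enumeration.
  # d80 = 80 km/h * 10 min, d95 = 95 km/h * 10 min; positions accumulate so
  # the sweep keeps fixes 1,2 (80), drops 3 (95), keeps 4 (implied (95+80)/2
  # = 87.5 over 20 min), drops 5, keeps 6.
  kmpd <- 111.19493
  d80 <- 80 / 6 / kmpd; d95 <- 95 / 6 / kmpd
  lat <- cumsum(c(0, d80, d95, d80, d95, d80))
  fx <- make_fixes(seq(0, 50, by = 10), lat = lat, lon = 0)
  out <- filter_speed(fx, vmax_kmh = 90)
  expect_equal(which(fx$lat %in% out$lat), c(1, 2, 4, 6))
})

test_that("speed filter is idempotent and bounds every kept consecutive speed", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 40
    fx <- make_fixes(seq(0, by = 5, length.out = n),
                     lat = cumsum(rnorm(n, 0, 0.05)),
                     lon = cumsum(rnorm(n, 0, 0.05)))
    f1 <- filter_speed(fx, vmax_kmh = 60)
    st <- track_steps(f1)
    expect_true(all(st$speed_kmh <= 60 + 1e-9, na.rm = TRUE))
    f2 <- filter_speed(f1, vmax_kmh = 60)
    expect_equal(attr(f2, "n_removed"), 0)
    expect_equal(nrow(f2), nrow(f1))
  }
})

test_that("resampling interpolates linearly on an exact arithmetic grid", {
  # already on a 10-min grid: a no-op
  fx <- make_fixes(c(0, 10, 20, 30), lat = c(0, 0.1, 0.15, 0.3), lon = c(0, 0.1, 0.2, 0.25))
  out <- resample_track(fx, 10)
  expect_equal(out$lat, fx$lat)
  expect_equal(out$lon, fx$lon)
  expect_equal(as.numeric(out$time), as.numeric(fx$time))

  # two fixes 10 min apart resampled at 5: exact midpoint appears
  fx <- make_fixes(c(0, 10), lat = c(0, 0.2), lon = c(10, 10.4))
  out <- resample_track(fx, 5)
  expect_equal(out$lat[2], 0.1)
  expect_equal(out$lon[2], 10.2)

  # irregular 7-fix track vs an independent piecewise-linear oracle
  set.seed(3)
  mins <- c(0, 7, 9, 16, 28, 31, 40)
  fx <- make_fixes(mins, lat = rnorm(7, 40, 0.1), lon = rnorm(7, 141, 0.1))
  out <- resample_track(fx, 5, max_gap_min = 60)
  grid <- seq(0, 40, by = 5)
  expect_equal(as.numeric(out$time - out$time[1], units = "mins"), grid)
  expect_equal(out$lat, approx(mins, fx$lat, xout = grid)$y)
  expect_equal(out$lon, approx(mins, fx$lon, xout = grid)$y)

  # re-resampling a gap-free resampled track at the same interval is a no-op
  out2 <- resample_track(out, 5, max_gap_min = 60)
  expect_equal(out2$lat, out$lat)
  expect_equal(out2$lon, out$lon)
})

test_that("resampling splits segments across long gaps instead of interpolating", {
  fx <- make_fixes(c(0, 10, 20, 120, 130), lat = c(0, 0.1, 0.2, 1, 1.1), lon = 0)
  out <- resample_track(fx, 10, max_gap_min = 30)
  expect_true(all(diff(as.numeric(out$time)) %% 600 == 0))
  expect_equal(sort(unique(out$segment)), c(1L, 2L))
  # no fabricated fixes strictly inside the 100-min outage
  inside <- out$time > fx$time[3] & out$time < fx$time[4]
  expect_equal(sum(inside), 0)
})

test_that("resampling interpolates across the antimeridian the short way", {
  fx <- make_fixes(c(0, 10), lat = 0, lon = c(179.9, -179.9))
  out <- resample_track(fx, 5)
  expect_equal(abs(out$lon[2]), 180)
})

test_that("GPS CSV round-trips and malformed rows are skipped", {
  fx <- make_fixes(c(0, 10, 20), lat = c(40, 40.1, 40.2), lon = 141, id = "B1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(fx, path)
  back <- read_track_csv(path)
  expect_equal(back$lat, fx$lat)
  expect_equal(as.numeric(back$time), as.numeric(fx$time))
  # inject a bad row
  lines <- readLines(path)
  writeLines(c(lines, "B1,not-a-time,40.3,141"), path)
  expect_message(back2 <- read_track_csv(path), "skipped 1")
  expect_equal(nrow(back2), 3)
})

test_that("track validation rejects duplicates and out-of-bounds coordinates", {
  fx <- make_fixes(c(0, 0), lat = c(0, 1), lon = 0)
  expect_error(validate_track(fx), "duplicate")
  expect_error(validate_track(make_fixes(0, 91, 0)), "latitude")
})
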