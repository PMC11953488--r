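test_that("dive_series enforces its invariants", {
  expect_error(dive_series("d", c(0, 5), c(0, 1)), "last depth")
  expect_error(dive_series("d", c(0, 5, 5, 10), c(0, 1, 2, 0)), "increasing")
  expect_error(dive_series("d", 0, 0), "2 samples")
  expect_error(dive_series("d", c(0, 5, 10), c(0, -1, 0)), ">= 0")
  expect_s3_class(dive_series("d", c(0, 10), c(0, 0)), "dive_series")
})

test_that("max depth, dive time and time of max behave on stated cases", {
  s <- dive_series("d", c(0, 5, 10, 30, 35), c(0, 20, 45, 20, 0))
  expect_identical(max_depth(s), 45)
  expect_identical(total_dive_time(s), 35)

  expect_identical(max_depth(dive_series("z", c(0, 10), c(0, 0))), 0)
  expect_identical(max_depth(dive_series("p", c(0, 5, 10), c(0, 30.5, 0))),
                   30.5)

  # offset invariance of dive time
  expect_identical(total_dive_time(dive_series("o", c(10, 60), c(0, 0))), 50)

  # first attainment, and the 0.1 m jitter tolerance
  s2 <- dive_series("m", c(0, 10, 20, 25), c(0, 30, 30, 0))
  expect_identical(time_of_max_depth(s2), 10)
  s3 <- dive_series("j", c(0, 8, 12, 18, 25), c(0, 29.95, 20, 30, 0))
  expect_identical(time_of_max_depth(s3), 8)
  expect_identical(time_of_max_depth(s3, tie_tol_m = 0.01), 18)
})

test_that("time_in_band is exact on closed-form cases", {
  flat <- dive_series("f", c(0, 0.01, 30, 30.01), c(0, 5, 5, 0))
  expect_equal(time_in_band(flat, 0, 10), 30.01, tolerance = 1e-12)

  ramp <- dive_series("r", c(0, 10, 20), c(0, 20, 0))
  expect_equal(time_in_band(ramp, 0, 10), 10)   # 5 up + 5 down
  expect_equal(time_in_band(ramp, 10, 20), 10)
  expect_equal(time_in_band(ramp, 0, 10, from_time = 10), 5)

  v <- dive_series("v", c(0, 10, 20), c(0, 40, 0))
  expect_equal(time_in_band(v, 0, 10), 5)
  expect_equal(time_in_band(v, 0, 10),
               oracle_time_in_band(v, 0, 10), tolerance = 0.01)

  expect_error(time_in_band(ramp, 10, 10), "lo < hi")
  expect_error(time_in_band(ramp, 0, 10, from_time = 25), "within")
})

test_that("half-open bands assign constant segments to the lower band", {
  s <- dive_series("c", c(0, 0.01, 10, 10.01), c(0, 10, 10, 0))
  expect_equal(time_in_band(s, 10, 20), 9.99)
  expect_equal(time_in_band(s, 0, 10), 0.02, tolerance = 1e-9)
})

test_that("band_features fills totals and after-max bands coherently", {
  flat <- dive_series("f", c(0, 0.001, 30, 30.001), c(0, 5, 5, 0))
  bf <- band_features(flat)
  expect_equal(unname(bf$total_band_min["0_10"]), 30.001)
  expect_equal(unname(sum(bf$total_band_min[-1])), 0)
  expect_equal(bf$after_max_band_min, bf$total_band_min - c(0.001, 0, 0, 0, 0),
               tolerance = 1e-9)

  ramp <- dive_series("r", c(0, 10, 20), c(0, 20, 0))
  bf <- band_features(ramp)
  expect_equal(unname(bf$total_band_min[c("0_10", "10_20")]), c(10, 10))
  expect_equal(unname(bf$after_max_band_min["0_10"]), 5)
  expect_equal(bf$time_of_max_min, 10)
})

test_that("band conservation and after-max dominance hold on random profiles", {
  profs <- random_profiles(100, seed = 4)
  for (s in profs) {
    bf <- band_features(s)
    expect_lt(abs(sum(bf$total_band_min) - bf$dive_time_min), 1e-9)
    expect_true(all(bf$after_max_band_min <= bf$total_band_min + 1e-9))
    expect_true(all(bf$total_band_min >= 0))
  }
})

test_that("analytic band times match the dense-grid oracle", {
  profs <- random_profiles(25, seed = 9)
  b <- list(lo = c(0, 10, 20, 30), hi = c(10, 20, 30, 40))
  for (s in profs) {
    for (i in seq_along(b$lo)) {
      expect_equal(time_in_band(s, b$lo[i], b$hi[i]),
                   oracle_time_in_band(s, b$lo[i], b$hi[i]),
                   tolerance = 0.01)
    }
  }
})

test_that("5-minute resampling perturbs band times by a bounded amount", {
  # a resampled trapezoid loses its vertices; the induced band-time error
  # stays within a couple of sampling intervals and conservation survives
  profs <- random_profiles(30, seed = 2)
  worst <- 0
  for (s in profs) {
    grid <- unique(c(seq(0, max(s$time_min), by = 5), max(s$time_min)))
    d <- stats::approx(s$time_min, s$depth_m, xout = grid)$y
    d[c(1, length(d))] <- 0
    rs <- dive_series(s$dive_id, grid, d)
    bf <- band_features(s); br <- band_features(rs)
    expect_lt(abs(sum(br$total_band_min) - br$dive_time_min), 1e-9)
    worst <- max(worst, abs(br$total_band_min - bf$total_band_min))
  }
  # documented resampling-error bound (minutes) for trapezoidal profiles
  expect_lt(worst, 10)
})

test_that("surface_interval caps, defaults and validates", {
  expect_identical(surface_interval(5, 3), 2)
  expect_identical(surface_interval(62, 2), 48)
  expect_identical(surface_interval(10, NULL), 48)
  expect_error(surface_interval(1, 2), "positive")
})
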