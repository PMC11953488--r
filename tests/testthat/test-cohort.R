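test_that("calibration satisfies the closed-form identities", {
  cal <- calibrate_variances(cohort_config())
  expect_equal(cal$tau2 / cal$sigma2, 12 / 71, tolerance = 1e-12)
  expect_equal(icc(cal$tau2, cal$sigma2), 0.12 / 0.83, tolerance = 1e-12)
  r2 <- nakagawa_r2(cal$fixed_effect_variance, cal$tau2, cal$sigma2)
  expect_equal(unname(r2), c(0.17, 0.29), tolerance = 1e-12)

  # scale equivariance: doubling all coefficients quadruples the variances
  cfg2 <- cohort_config(model = generative_model(
    b0 = 2 * -0.28489, b_depth = 2 * 0.02787, b_shallow = 2 * 0.00868,
    b_interaction = 2 * -0.00067))
  cal2 <- calibrate_variances(cfg2)
  expect_equal(cal2$tau2 / cal$tau2, 4, tolerance = 1e-9)
  expect_equal(cal2$sigma2 / cal$sigma2, 4, tolerance = 1e-9)
})

test_that("sampled divers match the configured distributions", {
  cfg <- cohort_config()
  set.seed(2)
  big <- sample_divers(cfg, n = 10000)
  # truncating to [18, 63] shifts the mean up by ~0.9 y; compare against
  # the truncated distribution's closed-form mean
  mu_t <- truncnorm::etruncnorm(18, 63, 38.2, 13.9)
  expect_lt(abs(mu_t - 38.2), 1)
  expect_lt(abs(mean(big$age_y) - mu_t), 3 * 13.9 / sqrt(10000))
  expect_true(all(big$age_y >= 18 & big$age_y <= 63))
  expect_equal(mean(big$sex == "F"), 13 / 59, tolerance = 0.01)
  cal <- calibrate_variances(cfg)
  expect_equal(sd(big$u), sqrt(cal$tau2), tolerance = 0.05)

  # gamma_age = 0 decouples age from the intercept
  cfg0 <- cohort_config(model = generative_model(gamma_age = 0))
  set.seed(3)
  d0 <- sample_divers(cfg0, n = 5000)
  expect_lt(abs(cor(d0$age_y, d0$u)), 0.05)

  # too strong a coupling is a config error
  cfgbad <- cohort_config(model = generative_model(gamma_age = 10))
  expect_error(sample_divers(cfgbad), "gamma_age")

  set.seed(4); a <- sample_divers(cfg, 50)
  set.seed(4); b <- sample_divers(cfg, 50)
  expect_identical(a, b)
})

test_that("dive plans respect bounds and the surface-interval schedule", {
  cfg <- cohort_config()
  set.seed(6)
  plans <- sample_dive_plan(cfg, 2000)
  expect_true(all(plans$depth_m >= 4 & plans$depth_m <= 45))
  expect_true(all(plans$duration_min >= 20 & plans$duration_min <= 90))
  expect_lt(abs(mean(plans$depth_m) - 24.2), 3 * 11 / sqrt(2000) + 0.3)
  expect_lt(abs(mean(plans$duration_min) - 50.4), 3 * 13.7 / sqrt(2000) + 0.3)
  expect_identical(plans$surface_interval_h[1], 48)
  second <- plans$dive_of_day == 2
  expect_true(all(plans$surface_interval_h[second] >= 1.5 &
                    plans$surface_interval_h[second] <= 3))
  first_later <- which(plans$dive_of_day == 1)[-1]
  expect_true(all(plans$surface_interval_h[first_later] == 16))
})

test_that("synth_profile realizes plans exactly", {
  p <- list(dive_id = "p1", depth_m = 30, duration_min = 50, stop_min = 4)
  s <- synth_profile(p)
  expect_equal(max_depth(s), 30)
  expect_equal(total_dive_time(s), 50)
  bf <- band_features(s)
  # after-max shallow time: stop + final two ascent legs through < 10 m
  expect_equal(unname(bf$after_max_band_min["0_10"]), 4 + 10 / 9,
               tolerance = 1e-9)
  expect_equal(unname(bf$after_max_band_min["0_10"]),
               oracle_time_in_band(s, 0, 10, from_time = bf$time_of_max_min),
               tolerance = 0.01)

  # minimum-depth plan: valid micro-trapezoid
  s4 <- synth_profile(list(dive_id = "p2", depth_m = 4, duration_min = 20,
                           stop_min = 10))
  expect_equal(max_depth(s4), 4)
  expect_equal(total_dive_time(s4), 20)

  expect_error(synth_profile(list(dive_id = "bad", depth_m = 45,
                                  duration_min = 6, stop_min = 0)),
               "infeasible")
})

test_that("synth_air integrates ambient pressure in closed form", {
  flat <- dive_series("f", c(0, 0.0001, 40, 40.0001), c(0, 10, 10, 0))
  expect_equal(synth_air(flat, 20), 1600, tolerance = 1)
  surf <- dive_series("s", c(0, 25), c(0, 0))
  expect_equal(synth_air(surf, 15), 15 * 25)
  ramp <- dive_series("r", c(0, 30, 30.0001), c(0, 30, 0))
  expect_equal(synth_air(ramp, 15), 1125, tolerance = 1)
  expect_error(synth_air(flat, 0), "> 0")
})

test_that("synth_grade reproduces the generative arithmetic", {
  m <- generative_model(sigma2 = 0, discretize = TRUE)
  quiet <- list(u = 0)
  g45 <- synth_grade(list(max_depth_m = 45, am_0_10 = 0), quiet, m)
  expect_equal(g45$latent_grade, exp(-0.28489 + 0.02787 * 45) - 1,
               tolerance = 1e-12)
  expect_identical(g45$eb_grade, 2L)
  g4 <- synth_grade(list(max_depth_m = 4, am_0_10 = 0), quiet, m)
  expect_lt(g4$latent_grade, 0)
  expect_identical(g4$eb_grade, 0L)
  # upper clamp
  g <- synth_grade(list(max_depth_m = 45, am_0_10 = 0), list(u = 10), m)
  expect_identical(g$eb_grade, 5L)
})

test_that("simulate_cohort produces a valid, reproducible linked dataset", {
  co <- default_cohort(1)
  expect_identical(nrow(co$divers), 59L)
  expect_identical(nrow(co$dives), 359L)
  expect_silent(validate_dives(co$dives))
  expect_silent(validate_divers(co$divers))
  expect_true(all(co$dives$diver_id %in% co$divers$diver_id))
  expect_setequal(unique(co$profiles$dive_id), co$dives$dive_id)

  co2 <- simulate_cohort(cohort_config(), seed = 1)
  expect_identical(co$dives, co2$dives)
  expect_identical(co$profiles, co2$profiles)

  co3 <- simulate_cohort(cohort_config(), seed = 2)
  expect_false(identical(co$dives$eb_grade, co3$dives$eb_grade))
})

test_that("the generated grade distribution is plausibly zero-inflated", {
  co <- default_cohort(1)
  p0 <- mean(co$dives$eb_grade == 0)
  expect_gt(p0, 0.5)
  expect_lt(p0, 0.9)
})

test_that("grades rise with depth and fall with shallow time at depth", {
  co <- default_cohort(1)
  d <- co$dives
  expect_gt(mean(d$eb_grade[d$max_depth_m > 30]),
            mean(d$eb_grade[d$max_depth_m < 15]))
  deep <- d[d$max_depth_m > 30, ]
  expect_lt(mean(deep$eb_grade[deep$am_0_10 > 15]),
            mean(deep$eb_grade[deep$am_0_10 < 5]))
  # age couples positively through the diver intercept
  m <- merge(d, co$divers, by = "diver_id")
  expect_gt(spearman_rho(m$age_y, m$eb_grade)$rho, 0)
})
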