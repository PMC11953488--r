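test_that("icc and nakagawa_r2 reproduce the published decomposition", {
  # variances in multiples of the fixed-effect variance that encode the
  # published pair (R2m, R2c) = (0.17, 0.29)
  expect_equal(icc(0.7059, 4.176), 0.1446, tolerance = 1e-3)
  expect_equal(icc(0, 2), 0)
  expect_equal(icc(1, 1e-12), 1, tolerance = 1e-9)
  expect_error(icc(1, 0), "> 0")

  r2 <- nakagawa_r2(1, 0.7059, 4.176)
  expect_equal(unname(round(r2, 2)), c(0.17, 0.29))
  expect_equal(unname(nakagawa_r2(3, 0, 0)), c(1, 1))
  r0 <- nakagawa_r2(0, 2, 6)
  expect_equal(unname(r0), c(0, icc(2, 6)))
  expect_error(nakagawa_r2(0, 0, 0), "positive")
})

test_that("icc equals (R2c - R2m) / (1 - R2m) identically", {
  set.seed(3)
  for (i in 1:50) {
    vf <- runif(1, 0, 2); t2 <- runif(1, 0, 2); s2 <- runif(1, 0.01, 2)
    r2 <- nakagawa_r2(vf, t2, s2)
    expect_equal(icc(t2, s2),
                 (r2[["r2_conditional"]] - r2[["r2_marginal"]]) /
                   (1 - r2[["r2_marginal"]]),
                 tolerance = 1e-12)
  }
})

test_that("fit_eb_mixed returns a coherent result on a simulated cohort", {
  co <- small_cohort(seed = 21, n_divers = 15, n_dives = 90)
  fit <- fit_eb_mixed(co$dives)
  expect_s3_class(fit, "eb_mixed_fit")
  expect_identical(fit$n_obs, 90L)
  expect_identical(fit$n_divers, 15L)
  expect_gte(fit$tau2, 0)
  expect_gt(fit$sigma2, 0)
  expect_equal(fit$icc, fit$tau2 / (fit$tau2 + fit$sigma2), tolerance = 1e-12)
  expect_true(fit$r2_marginal <= fit$r2_conditional)
  expect_true(fit$r2_conditional <= 1)
  # determinism: same data, same optimizer settings, same result
  fit2 <- fit_eb_mixed(co$dives)
  expect_identical(fit$coefficients, fit2$coefficients)
})

test_that("zero diver variance yields near-zero fitted ICC", {
  cfg <- cohort_config(n_divers = 20, n_dives_total = 120,
                       model = generative_model(tau2 = 0, gamma_age = 0,
                                                discretize = FALSE))
  iccs <- sapply(1:8, function(s) {
    co <- simulate_cohort(cfg, seed = 100 + s)
    fit_eb_mixed(co$dives, response = "latent_grade")$icc
  })
  expect_lt(mean(iccs), 0.05)
})

test_that("discretization preserves signs and significance at full n", {
  co <- default_cohort(1)
  fit <- fit_eb_mixed(co$dives)
  expect_gt(fit$coefficients["depth", "t"], 2)
  expect_lt(fit$coefficients["depth:shallow", "t"], -2)
  expect_gt(fit$b_shallow, 0)
})

test_that("standardized betas flip the shallow-time sign at covariate means", {
  co <- default_cohort(1)
  fit <- fit_eb_mixed(co$dives)
  # raw shallow-time coefficient positive, centred standardised beta
  # negative: the interaction dominates at the mean depth
  expect_gt(fit$b_shallow, 0)
  expect_lt(fit$beta_std[["shallow"]], 0)
  expect_gt(fit$beta_std[["depth"]], 0)

  # idempotence: standardising an already-standardised frame changes nothing
  std <- standardized_betas(co$dives)
  d2 <- co$dives
  d2$max_depth_m <- scale(d2$max_depth_m)[, 1]
  d2$am_0_10 <- scale(d2$am_0_10)[, 1]
  # z-scoring is idempotent, so pre-standardised predictors give the
  # same standardised fit
  std2 <- standardized_betas(d2)
  expect_equal(std$coefficients, std2$coefficients, tolerance = 1e-8)
})

test_that("pure-noise response gives small standardised betas", {
  co <- small_cohort(seed = 33, n_divers = 15, n_dives = 90)
  d <- co$dives
  set.seed(1)
  d$latent_grade <- exp(rnorm(nrow(d), 0, 0.4)) - 1
  std <- standardized_betas(d, response = "latent_grade")
  expect_true(all(abs(std$coefficients[-1, "estimate"]) < 0.35))
})

test_that("degenerate designs are rejected with guidance", {
  co <- small_cohort(seed = 21, n_divers = 15, n_dives = 90)
  one <- co$dives[co$dives$diver_id == co$dives$diver_id[1], ]
  expect_error(fit_eb_mixed(one), "fixed-effects")
  expect_error(fit_eb_mixed(co$dives[0, ]), "no observed grades")
})

test_that("correlation_table covers the expected rows with sane signs", {
  co <- default_cohort(1)
  tab <- correlation_table(co$dives, co$divers)
  expect_identical(nrow(tab), 12L)
  expect_gt(tab$rho[tab$variable == "Maximum depth (m)"], 0.2)
  expect_gt(tab$rho[tab$variable == "Field-formula prediction"], 0.2)
  # constant predictor flagged, not fatal
  d2 <- co$dives; d2$dive_of_day <- 1L
  tab2 <- correlation_table(d2, co$divers)
  expect_true(is.na(tab2$rho[tab2$variable ==
                               "First or second dive of the day"]))
  expect_match(tab2$note[tab2$variable == "First or second dive of the day"],
               "constant")
  # holm adjustment is monotone in the raw p-values
  tab3 <- correlation_table(co$dives, co$divers, adjust = "holm")
  expect_true(all(tab3$p_adj >= tab3$p))
})
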