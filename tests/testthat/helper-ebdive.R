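# shared fixtures, built in code

# simple symmetric trapezoid: surface -> depth -> surface
trapezoid_series <- function(depth = 30, duration = 45, id = "trap",
                             n_bottom = 2) {
  desc <- depth / 18
  asc <- depth / 9
  bottom <- duration - desc - asc
  stopifnot(bottom > 0)
  dive_series(id,
              c(0, desc, desc + bottom, duration),
              c(0, depth, depth, 0))
}

# dense-grid numerical oracle for time_in_band: occupancy fraction of a
# fine midpoint grid, independent of the analytic implementation
oracle_time_in_band <- function(series, lo, hi, from_time = 0, dt = 0.001) {
  t0 <- max(from_time, series$time_min[1])
  t1 <- series$time_min[length(series$time_min)]
  if (t1 <= t0) return(0)
  mid <- seq(t0 + dt / 2, t1, by = dt)
  d <- stats::approx(series$time_min, series$depth_m, xout = mid)$y
  sum(d >= lo & d < hi) * dt
}

# random valid profiles drawn through the generator's plan distribution
random_profiles <- function(n, seed = 1) {
  cfg <- cohort_config()
  set.seed(seed)
  plans <- sample_dive_plan(cfg, n)
  lapply(seq_len(n), function(i) {
    p <- plans[i, ]; p$dive_id <- paste0("R", i)
    synth_profile(p)
  })
}

# memoised small simulated cohorts so multiple test files can share them
.cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function(seed = 11, n_divers = 12, n_dives = 72,
                         discretize = TRUE) {
  key <- paste(seed, n_divers, n_dives, discretize, sep = "_")
  if (is.null(.cohort_cache[[key]])) {
    cfg <- cohort_config(n_divers = n_divers, n_dives_total = n_dives,
                         model = generative_model(discretize = discretize))
    .cohort_cache[[key]] <- simulate_cohort(cfg, seed = seed)
  }
  .cohort_cache[[key]]
}

default_cohort <- function(seed = 1) {
  key <- paste0("default_", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(cohort_config(), seed = seed)
  }
  .cohort_cache[[key]]
}
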