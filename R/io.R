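#' Write a cohort to the three-file CSV dialect
#'
#' Emits `profiles.csv` (`dive_id`, `time_min`, `depth_m`), `dives.csv`
#' (record table) and `divers.csv` (`diver_id`, `age_y`, `sex`, `bmi`)
#' into `dir`. UTF-8, header row, `'.'` decimal separator. Latent
#' simulation-only columns (`u`, `sac_lmin`, `latent_grade`) are kept when
#' `keep_latent = TRUE` (default) so simulated cohorts round-trip exactly.
#'
#' @param cohort a `dive_cohort` (or list with `divers`, `dives`,
#'   `profiles`).
#' @param dir output directory (created if needed).
#' @param keep_latent keep simulation-only columns.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, keep_latent = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  divers <- cohort$divers
  dives <- cohort$dives
  if (!keep_latent) {
    divers <- divers[setdiff(names(divers), c("u", "sac_lmin"))]
    dives <- dives[setdiff(names(dives), "latent_grade")]
  }
  paths <- file.path(dir, c("divers.csv", "dives.csv", "profiles.csv"))
  utils::write.csv(divers, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(dives, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$profiles, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a cohort from the three-file CSV dialect
#'
#' Reads and cross-validates `divers.csv`, `dives.csv` and (optionally)
#' `profiles.csv` from `dir`. Unknown extra columns are tolerated with a
#' warning; schema violations, duplicate ids and dives referencing
#' missing divers are errors naming the offending ids.
#'
#' @param dir directory containing the CSV files.
#' @param require_profiles error if `profiles.csv` is absent (default
#'   `FALSE`: the record table already carries all derived features).
#' @return A list of class `dive_cohort` with `divers`, `dives`,
#'   `profiles` (`NULL` if absent).
#' @export
read_cohort <- function(dir, require_profiles = FALSE) {
  pd <- file.path(dir, "divers.csv")
  pv <- file.path(dir, "dives.csv")
  pp <- file.path(dir, "profiles.csv")
  for (p in c(pd, pv)) {
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
  }
  divers <- utils::read.csv(pd, stringsAsFactors = FALSE)
  dives <- utils::read.csv(pv, stringsAsFactors = FALSE)
  validate_divers(divers)
  validate_dives(dives)
  known <- c("diver_id", "age_y", "sex", "bmi", "sac_lmin", "u")
  extra <- setdiff(names(divers), known)
  if (length(extra)) {
    warning("ignoring unknown diver columns: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  orphan <- setdiff(dives$diver_id, divers$diver_id)
  if (length(orphan)) {
    stop("dives reference unknown diver_id: ",
         paste(unique(orphan), collapse = ", "), call. = FALSE)
  }
  profiles <- NULL
  if (file.exists(pp)) {
    profiles <- utils::read.csv(pp, stringsAsFactors = FALSE)
    need <- c("dive_id", "time_min", "depth_m")
    miss <- setdiff(need, names(profiles))
    if (length(miss)) {
      stop("profiles.csv is missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    op <- setdiff(unique(profiles$dive_id), dives$dive_id)
    if (length(op)) {
      stop("profiles reference unknown dive_id: ",
           paste(op, collapse = ", "), call. = FALSE)
    }
  } else if (require_profiles) {
    stop("missing input file: ", pp, call. = FALSE)
  }
  structure(list(divers = divers, dives = dives, profiles = profiles,
                 config = NULL, seed = NA_integer_), class = "dive_cohort")
}

#' Distribution of observed EB grades
#'
#' @param dives dive-record table with observed grades.
#' @return data.frame with one row per grade 0-5 plus an aggregate
#'   `">=1"` row: `grade`, `count`, `percent`.
#' @export
eb_distribution <- function(dives) {
  g <- dives$eb_grade
  g <- g[!is.na(g)]
  if (!length(g)) stop("no observed grades", call. = FALSE)
  counts <- as.integer(table(factor(g, levels = 0:5)))
  out <- data.frame(grade = c(as.character(0:5), ">=1"),
                    count = c(counts, sum(counts[-1])),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$count / length(g)
  out
}

#' Write the full analysis report for a cohort
#'
#' Runs the whole pipeline on a cohort with observed grades and writes,
#' into `out_dir`: the grade distribution, the predictor correlation
#' table, the mixed-model summary (raw and standardised coefficients plus
#' the variance decomposition), the random-forest variable-set
#' comparison, the field-formula evaluation (correlation and the
#' observed-vs-predicted cross-table), and a run manifest with the seed
#' and input digests. Reruns with the same cohort and seed are
#' byte-identical. Cohorts without grades get the degraded report:
#' formula predictions only, plus an explicit notice.
#'
#' @param cohort a `dive_cohort` with grades.
#' @param out_dir output directory.
#' @param seed seed for the stochastic steps (forest split/fits).
#' @param ntree trees per forest.
#' @return Invisibly, the paths written.
#' @export
make_report <- function(cohort, out_dir, seed = 1L, ntree = 500) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on.exit({
    # remove partial output on failure
    if (!isTRUE(attr(written, "done"))) unlink(written)
  })
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     p, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  dives <- cohort$dives
  divers <- cohort$divers
  graded <- !all(is.na(dives$eb_grade))
  if (graded) {
    emit(eb_distribution(dives), "grade_distribution.csv")
    emit(correlation_table(dives, divers), "correlations.csv")
    fit <- fit_eb_mixed(dives)
    mm <- data.frame(term = rownames(fit$coefficients),
                     estimate = fit$coefficients[, "estimate"],
                     se = fit$coefficients[, "se"],
                     t = fit$coefficients[, "t"],
                     beta_std = fit$beta_std)
    mm2 <- data.frame(term = c("tau2", "sigma2", "icc", "r2_marginal",
                               "r2_conditional", "n_obs", "n_divers"),
                      estimate = c(fit$tau2, fit$sigma2, fit$icc,
                                   fit$r2_marginal, fit$r2_conditional,
                                   fit$n_obs, fit$n_divers),
                      se = NA, t = NA, beta_std = NA)
    emit(rbind(mm, mm2), "mixed_model.csv")
    emit(rf_variable_set_eval(dives, divers, seed = seed, ntree = ntree),
         "ml_comparison.csv")
    ev <- evaluate_formula(dives, divers)
    emit(data.frame(metric = c("spearman_rho", "p", "n"),
                    value = c(ev$rho, ev$p, ev$n)), "formula_evaluation.csv")
    ct <- as.data.frame.matrix(ev$cross_table)
    ct <- cbind(observed_grade = rownames(ct), ct)
    emit(ct, "formula_cross_table.csv")
  } else {
    m <- merge(dives, divers, by = "diver_id", sort = FALSE)
    pred <- predict_eb(m$age_y, m$surface_interval_h, m$max_depth_m,
                       m$air_consumption_barl)
    emit(data.frame(dive_id = m$dive_id,
                    predicted_grade = pred$predicted_grade,
                    risk_class = pred$risk_class), "formula_predictions.csv")
    writeLines(paste("NOTICE: cohort has no observed EB grades;",
                     "report restricted to field-formula predictions."),
               np <- file.path(out_dir, "NOTICE.txt"))
    written <- c(written, np)
  }
  manifest <- run_manifest(cohort, seed, written)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  written <- c(written, mp)
  attr(written, "done") <- TRUE
  invisible(written)
}

# md5 digest of a data.frame via its CSV serialization
df_digest <- function(df) {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  utils::write.csv(df, tf, row.names = FALSE)
  unname(tools::md5sum(tf))
}

run_manifest <- function(cohort, seed, written) {
  list(tool = "ebdive",
       version = as.character(utils::packageVersion("ebdive")),
       seed = seed,
       cohort_seed = cohort$seed,
       n_divers = nrow(cohort$divers),
       n_dives = nrow(cohort$dives),
       input_digests = list(
         divers = df_digest(cohort$divers),
         dives = df_digest(cohort$dives)),
       outputs = basename(written))
}
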