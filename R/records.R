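#' @keywords internal
band_cols <- function() {
  lab <- eb_bands()$label
  list(total = paste0("t_", lab), after = paste0("am_", lab))
}

#' Assemble a dive record from a profile and metadata
#'
#' Combines a depth-time profile with per-dive metadata and the diver's
#' covariates into one row holding every predictor used downstream:
#' maximum depth, dive time, band times (total and after maximum depth),
#' surface interval, air consumption, dive-of-day flag and, when observed,
#' the EB bubble grade.
#'
#' @param series a [dive_series()].
#' @param dive_meta a list (or one-row data.frame) with elements
#'   `air_consumption_barl`, `dive_of_day` (1 = first dive of the day,
#'   2 = second), and either `surface_interval_h` or both `start_h` and
#'   `previous_end_h` (hours; `previous_end_h = NULL`/`NA` for a trip's
#'   first dive). Optional: `eb_grade` (integer 0-5), `day_index`,
#'   `start_min_of_day`.
#' @param diver a list or one-row data.frame with at least `diver_id`.
#' @return A one-row `data.frame` with the full dive record.
#' @export
extract_record <- function(series, dive_meta, diver) {
  series <- as_dive_series(series)
  meta <- as.list(dive_meta)
  need <- c("air_consumption_barl", "dive_of_day")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("dive_meta is missing required fields: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.null(meta$surface_interval_h)) {
    si <- meta$surface_interval_h
    if (!is.finite(si) || si <= 0 || si > 48) {
      stop("surface_interval_h must be in (0, 48]", call. = FALSE)
    }
  } else if (!is.null(meta$start_h)) {
    si <- surface_interval(meta$start_h, meta$previous_end_h)
  } else {
    stop("dive_meta must supply surface_interval_h or start_h/previous_end_h",
         call. = FALSE)
  }
  grade <- meta$eb_grade
  if (is.null(grade)) grade <- NA_integer_
  if (!is.na(grade)) {
    if (!grade %in% 0:5) stop("eb_grade must be an integer in 0..5",
                              call. = FALSE)
    grade <- as.integer(grade)
  }
  if (!meta$dive_of_day %in% 1:2) {
    stop("dive_of_day must be 1 or 2", call. = FALSE)
  }
  if (meta$air_consumption_barl < 0) {
    stop("air_consumption_barl must be >= 0", call. = FALSE)
  }
  bf <- band_features(series)
  bc <- band_cols()
  rec <- data.frame(
    dive_id = series$dive_id,
    diver_id = as.list(diver)$diver_id,
    day_index = if (is.null(meta$day_index)) NA_integer_ else
      as.integer(meta$day_index),
    dive_of_day = as.integer(meta$dive_of_day),
    start_min_of_day = if (is.null(meta$start_min_of_day)) NA_real_ else
      as.numeric(meta$start_min_of_day),
    surface_interval_h = si,
    air_consumption_barl = as.numeric(meta$air_consumption_barl),
    max_depth_m = bf$max_depth_m,
    dive_time_min = bf$dive_time_min,
    time_of_max_min = bf$time_of_max_min,
    eb_grade = grade,
    stringsAsFactors = FALSE
  )
  rec[bc$total] <- as.list(bf$total_band_min)
  rec[bc$after] <- as.list(bf$after_max_band_min)
  rec
}

#' Validate a table of dive records
#'
#' Checks the invariants every dive record must satisfy: grades in 0..5
#' when present, surface intervals in (0, 48], band times non-negative,
#' total band times summing to dive time, and after-max band times bounded
#' by their totals.
#'
#' @param dives a data.frame of dive records as produced by
#'   [extract_record()] or [simulate_cohort()].
#' @param tol tolerance for the band-time conservation check (minutes).
#' @return `dives`, invisibly, if valid; otherwise an error.
#' @export
validate_dives <- function(dives, tol = 1e-9) {
  stopifnot(is.data.frame(dives))
  bc <- band_cols()
  need <- c("dive_id", "diver_id", "dive_of_day", "surface_interval_h",
            "air_consumption_barl", "max_depth_m", "dive_time_min",
            "eb_grade", bc$total, bc$after)
  miss <- setdiff(need, names(dives))
  if (length(miss)) {
    stop("dive table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(dives$dive_id)) {
    stop("duplicate dive_id in dive table", call. = FALSE)
  }
  g <- dives$eb_grade
  bad <- which(!is.na(g) & !(g %in% 0:5))
  if (length(bad)) {
    stop("eb_grade outside 0..5 at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(dives$surface_interval_h > 0 & dives$surface_interval_h <= 48))
  if (length(bad)) {
    stop("surface_interval_h outside (0, 48] at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tot <- as.matrix(dives[bc$total])
  aft <- as.matrix(dives[bc$after])
  if (any(tot < 0) || any(aft < 0)) {
    stop("negative band times", call. = FALSE)
  }
  bad <- which(abs(rowSums(tot) - dives$dive_time_min) > tol)
  if (length(bad)) {
    stop("band times do not sum to dive time at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(rowSums(aft > tot + tol) > 0)
  if (length(bad)) {
    stop("after-max band time exceeds total band time at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(dives)
}

#' Validate a table of divers
#'
#' @param divers a data.frame with columns `diver_id`, `age_y`, `sex`
#'   (`"F"`/`"M"`), `bmi`.
#' @return `divers`, invisibly, if valid.
#' @export
validate_divers <- function(divers) {
  stopifnot(is.data.frame(divers))
  need <- c("diver_id", "age_y", "sex", "bmi")
  miss <- setdiff(need, names(divers))
  if (length(miss)) {
    stop("diver table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(divers$diver_id)) {
    stop("duplicate diver_id in diver table", call. = FALSE)
  }
  if (any(!divers$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }
  if (any(divers$age_y <= 0 | divers$bmi <= 0)) {
    stop("age_y and bmi must be positive", call. = FALSE)
  }
  invisible(divers)
}
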