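#' Depth-time series for a single dive
#'
#' A `dive_series` holds one dive's sampled depth trajectory. Depth is
#' positive-down in metres, time in minutes from the start of the dive.
#' The trajectory is interpreted as piecewise linear between samples, which
#' makes every band-time computation closed form.
#'
#' @param dive_id scalar identifier for the dive.
#' @param time_min numeric vector of sample times in minutes, strictly
#'   increasing, at least two samples.
#' @param depth_m numeric vector of sampled depths in metres, all `>= 0`;
#'   the first and last depth must be 0 (a dive starts and ends at the
#'   surface).
#'
#' @return An object of class `dive_series`: a list with elements
#'   `dive_id`, `time_min`, `depth_m`.
#' @examples
#' s <- dive_series("d1", c(0, 5, 10, 30, 35), c(0, 20, 45, 20, 0))
#' max_depth(s)
#' total_dive_time(s)
#' @export
dive_series <- function(dive_id, time_min, depth_m) {
  time_min <- as.numeric(time_min)
  depth_m <- as.numeric(depth_m)
  if (length(dive_id) != 1L) stop("dive_id must be a scalar", call. = FALSE)
  n <- length(time_min)
  if (n != length(depth_m)) {
    stop("time_min and depth_m must have equal length", call. = FALSE)
  }
  if (n < 2L) stop("a dive series needs at least 2 samples", call. = FALSE)
  if (anyNA(time_min) || anyNA(depth_m)) {
    stop("dive series samples must not contain NA", call. = FALSE)
  }
  if (any(diff(time_min) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  if (any(depth_m < 0)) stop("depths must be >= 0", call. = FALSE)
  if (depth_m[1L] != 0 || depth_m[n] != 0) {
    stop("first and last depth must be 0 (dive starts and ends at surface)",
         call. = FALSE)
  }
  structure(list(dive_id = dive_id, time_min = time_min, depth_m = depth_m),
            class = "dive_series")
}

#' @export
print.dive_series <- function(x, ...) {
  cat(sprintf("<dive_series %s: %d samples, %.1f min, max depth %.1f m>\n",
              as.character(x$dive_id), length(x$time_min),
              total_dive_time(x), max_depth(x)))
  invisible(x)
}

as_dive_series <- function(x) {
  if (inherits(x, "dive_series")) return(x)
  stop("expected a dive_series object", call. = FALSE)
}

#' Maximum depth of a dive
#'
#' Under piecewise-linear interpolation the trajectory maximum is always
#' attained at a sample, so this is simply the deepest sample.
#'
#' @param series a [dive_series()].
#' @return Maximum depth in metres.
#' @export
max_depth <- function(series) {
  series <- as_dive_series(series)
  max(series$depth_m)
}

#' Total dive time
#'
#' @param series a [dive_series()].
#' @return Last sample time minus first sample time, in minutes.
#' @export
total_dive_time <- function(series) {
  series <- as_dive_series(series)
  t <- series$time_min
  t[length(t)] - t[1L]
}

#' Time of first attainment of maximum depth
#'
#' Returns the time of the first sample within `tie_tol_m` of the maximum
#' depth. The tolerance makes "after maximum depth" robust to depth-sensor
#' jitter: a 29.95 m reading followed by 30.0 m counts as the same maximum
#' under the default 0.1 m tolerance, and the earlier time is used.
#'
#' @param series a [dive_series()].
#' @param tie_tol_m depths within this tolerance of the maximum count as
#'   attaining it (default 0.1 m).
#' @return Time in minutes of the first attainment of the maximum depth.
#' @export
time_of_max_depth <- function(series, tie_tol_m = 0.1) {
  series <- as_dive_series(series)
  dmax <- max(series$depth_m)
  series$time_min[which(series$depth_m >= dmax - tie_tol_m)[1L]]
}

#' Time spent inside a depth band
#'
#' Computes the total time with `lo <= depth < hi` for `t >= from_time`,
#' analytically on the piecewise-linear trajectory (exact boundary-crossing
#' times, not sample counting). Bands are half-open so that the standard
#' 10-metre bands partition depth and band times sum exactly to dive time.
#'
#' @param series a [dive_series()].
#' @param lo,hi band bounds in metres, `0 <= lo < hi` (`hi` may be `Inf`).
#' @param from_time only count time at or after this minute (default 0,
#'   i.e. the whole dive); must lie within the sampled time range.
#' @return Minutes spent in the band.
#' @examples
#' s <- dive_series("d", c(0, 10, 20), c(0, 40, 0))
#' time_in_band(s, 0, 10)   # 5: 2.5 min on descent + 2.5 min on ascent
#' @export
time_in_band <- function(series, lo, hi, from_time = 0) {
  series <- as_dive_series(series)
  if (!is.finite(lo) || lo < 0 || lo >= hi) {
    stop("band bounds must satisfy 0 <= lo < hi", call. = FALSE)
  }
  t <- series$time_min
  d <- series$depth_m
  if (from_time < t[1L] || from_time > t[length(t)]) {
    stop("from_time must lie within the sampled time range", call. = FALSE)
  }
  # clip the trajectory to [from_time, end]
  if (from_time > t[1L]) {
    d0 <- stats::approx(t, d, xout = from_time)$y
    keep <- t > from_time
    t <- c(from_time, t[keep])
    d <- c(d0, d[keep])
    if (length(t) < 2L) return(0)
  }
  t0 <- t[-length(t)]; t1 <- t[-1L]
  d0 <- d[-length(d)]; d1 <- d[-1L]
  dt <- t1 - t0
  flat <- d0 == d1
  # constant segments: half-open membership decides in full
  tot <- sum(dt[flat & d0 >= lo & d0 < hi])
  # sloped segments: occupancy time = depth-overlap length / |slope|;
  # endpoints have measure zero so the closed overlap is exact
  if (any(!flat)) {
    s0 <- d0[!flat]; s1 <- d1[!flat]; sdt <- dt[!flat]
    dl <- pmin(s0, s1); dh <- pmax(s0, s1)
    ov <- pmax(0, pmin(dh, hi) - pmax(dl, lo))
    tot <- tot + sum(ov * sdt / (dh - dl))
  }
  tot
}

# the five internal depth bands; the fifth keeps band conservation exact for
# dives deeper than 40 m even though reports expose only the four shallow ones
eb_bands <- function() {
  list(lo = c(0, 10, 20, 30, 40), hi = c(10, 20, 30, 40, Inf),
       label = c("0_10", "10_20", "20_30", "30_40", "40_plus"))
}

#' Depth-band features of a dive profile
#'
#' Computes, for the 10-metre depth bands `[0,10)`, `[10,20)`, `[20,30)`,
#' `[30,40)` and `[40,Inf)`, the total minutes spent in each band and the
#' minutes spent in each band after the first attainment of maximum depth,
#' together with maximum depth, total dive time and the time of the maximum.
#' Total band times partition the dive, so they sum exactly to dive time.
#'
#' @param series a [dive_series()].
#' @return A list of class `band_features` with elements `total_band_min`
#'   and `after_max_band_min` (named numeric vectors over the five bands),
#'   `max_depth_m`, `dive_time_min` and `time_of_max_min`.
#' @export
band_features <- function(series) {
  series <- as_dive_series(series)
  b <- eb_bands()
  tmax <- time_of_max_depth(series)
  total <- after <- numeric(length(b$lo))
  for (i in seq_along(b$lo)) {
    total[i] <- time_in_band(series, b$lo[i], b$hi[i])
    after[i] <- time_in_band(series, b$lo[i], b$hi[i], from_time = tmax)
  }
  names(total) <- names(after) <- b$label
  structure(list(total_band_min = total,
                 after_max_band_min = after,
                 max_depth_m = max_depth(series),
                 dive_time_min = total_dive_time(series),
                 time_of_max_min = tmax),
            class = "band_features")
}

#' Surface interval before a dive
#'
#' Elapsed hours between the end of the previous dive and the start of the
#' current one, capped at 48 h. The cap reflects full inert-gas
#' desaturation: beyond 48 h the residual load is treated as zero, so a
#' trip's first dive (no previous dive) also gets 48 h.
#'
#' @param current_start start of the current dive (hours, or anything
#'   subtractable yielding hours, e.g. minutes / 60 upstream).
#' @param previous_end end of the previous dive on the same scale, or `NULL`
#'   for the first dive of a trip.
#' @param cap_h saturation cap in hours (default 48).
#' @return Surface interval in hours, in `(0, cap_h]`.
#' @export
surface_interval <- function(current_start, previous_end = NULL, cap_h = 48) {
  if (is.null(previous_end) || is.na(previous_end)) return(cap_h)
  si <- as.numeric(current_start) - as.numeric(previous_end)
  if (si <= 0) stop("surface interval must be positive", call. = FALSE)
  min(si, cap_h)
}
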