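#' Field formula for predicting the post-dive EB bubble grade
#'
#' The four-parameter field formula combines diver age, the surface
#' interval before the dive, maximum depth and total breathing-gas
#' consumption into a predicted Eftedal-Brubakk bubble grade:
#'
#' \deqn{\widehat{EB} = \left(\frac{age}{50} - \frac{SI}{150} +
#'   \frac{depth}{45} + \frac{air}{4500}\right)^2}
#'
#' with age in years, surface interval SI in hours (saturating at 48 h,
#' capped upstream by [surface_interval()]), depth in metres and air
#' consumption in bar-litres. The coefficients are fixed constants from the
#' original derivation and are not refit here. Being a square, the
#' prediction is non-negative; a clamped version on the observable 0-5
#' grade scale is also returned.
#'
#' @param age years, `>= 0`.
#' @param surface_interval hours, in `[0, 48]`.
#' @param max_depth metres, `>= 0`.
#' @param air_consumption bar-litres, `>= 0`.
#' @return A list of class `eb_prediction` with `predicted_grade`
#'   (unclamped), `predicted_grade_clamped` (`min(., 5)`) and `risk_class`.
#'   All elements are vectorised over the inputs.
#' @examples
#' predict_eb(50, 48, 45, 4500)  # 7.1824
#' @export
predict_eb <- function(age, surface_interval, max_depth, air_consumption) {
  if (any(age < 0) || any(surface_interval < 0) || any(max_depth < 0) ||
      any(air_consumption < 0)) {
    stop("all formula inputs must be >= 0", call. = FALSE)
  }
  if (any(surface_interval > 48)) {
    stop("surface_interval must be capped at 48 h (see surface_interval())",
         call. = FALSE)
  }
  g <- (age / 50 - surface_interval / 150 +
          max_depth / 45 + air_consumption / 4500)^2
  structure(list(predicted_grade = g,
                 predicted_grade_clamped = pmin(g, 5),
                 risk_class = risk_class(g)),
            class = "eb_prediction")
}

#' @export
print.eb_prediction <- function(x, ...) {
  df <- data.frame(predicted_grade = x$predicted_grade,
                   clamped = x$predicted_grade_clamped,
                   risk_class = x$risk_class)
  print(df, row.names = nrow(df) > 1)
  invisible(x)
}

#' Risk class of a predicted grade
#'
#' Maps a predicted grade to `low` / `elevated` / `high`. The default
#' cut-points (1 and 2 on the predicted-grade scale) are a package
#' convention: risk classes are mentioned in the field but no published
#' cut-points exist, so they are configurable.
#'
#' @param pred numeric predicted grade(s), or an `eb_prediction`.
#' @param thresholds length-2 increasing numeric: lower bounds of the
#'   `elevated` and `high` classes.
#' @return Character vector in `{"low","elevated","high"}`.
#' @export
risk_class <- function(pred, thresholds = c(1, 2)) {
  if (inherits(pred, "eb_prediction")) pred <- pred$predicted_grade
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  cls <- c("low", "elevated", "high")
  cls[findInterval(pred, thresholds) + 1L]
}

#' Evaluate the field formula against observed grades
#'
#' Computes the formula prediction for every dive with an observed grade,
#' the Spearman rank correlation between predicted and observed grades, and
#' a 6 x 6 cross-table of rounded clamped predictions versus observed
#' grades.
#'
#' @param dives dive-record table (see [validate_dives()]) with observed
#'   `eb_grade` for at least 3 dives.
#' @param divers diver table (see [validate_divers()]).
#' @return A list of class `eb_formula_eval` with `rho`, `p`,
#'   `cross_table` (observed grade in rows, rounded prediction in columns)
#'   and `predicted` (the per-dive unclamped predictions).
#' @export
evaluate_formula <- function(dives, divers) {
  validate_divers(divers)
  m <- merge(dives, divers, by = "diver_id", sort = FALSE)
  m <- m[!is.na(m$eb_grade), ]
  if (nrow(m) < 3L) {
    stop("need at least 3 dives with observed grades", call. = FALSE)
  }
  pred <- predict_eb(m$age_y, m$surface_interval_h, m$max_depth_m,
                     m$air_consumption_barl)
  ct <- table(observed = factor(m$eb_grade, levels = 0:5),
              predicted = factor(pmin(round(pred$predicted_grade_clamped), 5),
                                 levels = 0:5))
  rs <- spearman_rho(pred$predicted_grade, m$eb_grade)
  structure(list(rho = rs$rho, p = rs$p, cross_table = ct,
                 predicted = pred$predicted_grade, n = nrow(m)),
            class = "eb_formula_eval")
}

#' @export
print.eb_formula_eval <- function(x, ...) {
  cat(sprintf("Field-formula evaluation on %d dives\n", x$n))
  cat(sprintf("  Spearman rho = %.3f (p = %.3g)\n", x$rho, x$p))
  cat("  observed (rows) vs rounded clamped prediction (cols):\n")
  print(x$cross_table)
  invisible(x)
}
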