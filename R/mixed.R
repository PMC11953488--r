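#' Linear mixed-effects model of the log bubble grade
#'
#' Fits, by restricted maximum likelihood via \pkg{lme4},
#'
#' \deqn{\log(grade + 1) \sim depth + shallow + depth{:}shallow + (1 | diver)}
#'
#' where `depth` is maximum depth (m), `shallow` is the time spent between
#' 0 and 10 m after maximum depth (min), and the random intercept absorbs
#' the repeated measures per diver. The natural logarithm is used. Besides
#' the raw coefficients the fit reports the variance decomposition:
#' between-diver variance `tau2`, residual variance `sigma2`, the
#' intraclass correlation `tau2 / (tau2 + sigma2)`, and marginal /
#' conditional R-squared computed from the variance of the fitted
#' fixed-effect predictor (see [nakagawa_r2()]). Standardised coefficients
#' come from a second fit on z-scored response and predictors
#' ([standardized_betas()]).
#'
#' A fit in which the between-diver variance collapses to zero is reported
#' with `tau2 = 0` and `singular = TRUE` rather than raising an error.
#'
#' @param dives dive-record table with grades; needs at least 2 divers,
#'   each contributing at least 2 dives.
#' @param response column used as the observed grade: `"eb_grade"`
#'   (default) or `"latent_grade"` for simulated continuous grades.
#' @return An object of class `eb_mixed_fit`; see Details for fields.
#' @export
fit_eb_mixed <- function(dives, response = "eb_grade") {
  df <- mixed_frame(dives, response)
  fit <- lme4::lmer(y ~ depth + shallow + depth:shallow + (1 | diver_id),
                    data = df, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  res <- mixed_summary(fit, df)
  res$beta_std <- standardized_betas(dives, response)$coefficients[, "estimate"]
  res
}

# shared preparation/validation for the raw and standardized fits
mixed_frame <- function(dives, response) {
  stopifnot(is.data.frame(dives))
  if (!response %in% names(dives)) {
    stop("response column '", response, "' not found", call. = FALSE)
  }
  g <- dives[[response]]
  keep <- !is.na(g)
  if (!any(keep)) stop("no observed grades", call. = FALSE)
  df <- data.frame(y = log(g[keep] + 1),
                   depth = dives$max_depth_m[keep],
                   shallow = dives$am_0_10[keep],
                   diver_id = factor(dives$diver_id[keep]))
  tab <- table(df$diver_id)
  if (length(tab) < 2L) {
    stop("only one diver: fit a fixed-effects model instead (lm)",
         call. = FALSE)
  }
  if (sum(tab >= 2L) < 2L) {
    stop("need at least 2 divers with >= 2 dives each", call. = FALSE)
  }
  df
}

mixed_summary <- function(fit, df) {
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == "diver_id"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  X <- stats::model.matrix(fit)
  vf <- stats::var(as.vector(X %*% fe))
  r2 <- nakagawa_r2(vf, tau2, sigma2)
  structure(list(
    coefficients = cbind(estimate = fe, se = se, t = fe / se),
    b0 = unname(fe[1]), b_depth = unname(fe["depth"]),
    b_shallow = unname(fe["shallow"]),
    b_interaction = unname(fe["depth:shallow"]),
    tau2 = tau2, sigma2 = sigma2, fixed_effect_variance = vf,
    icc = icc(tau2, sigma2),
    r2_marginal = r2[["r2_marginal"]],
    r2_conditional = r2[["r2_conditional"]],
    singular = lme4::isSingular(fit, tol = 1e-8),
    n_obs = nrow(df), n_divers = nlevels(df$diver_id),
    fit = fit), class = "eb_mixed_fit")
}

#' @export
print.eb_mixed_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Mixed model of log(grade + 1): %d dives, %d divers%s\n",
              x$n_obs, x$n_divers, if (x$singular) " (singular fit)" else ""))
  print(round(x$coefficients, 5))
  cat(sprintf("tau2 = %.4g, sigma2 = %.4g, ICC = %.3f\n",
              x$tau2, x$sigma2, x$icc))
  cat(sprintf("R2 marginal = %.3f, R2 conditional = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  if (!is.null(x$beta_std)) {
    cat("standardised betas:\n"); print(round(x$beta_std, 3))
  }
  invisible(x)
}

#' Standardised coefficients of the log-grade mixed model
#'
#' Z-scores the response and both main-effect predictors (mean 0, SD 1)
#' *before* forming the interaction, then refits the mixed model. Because
#' the predictors are centred first, the standardised main effects
#' represent effects at the covariate means; with an interaction whose
#' sign opposes the raw main effect this can (correctly) flip the sign of
#' a standardised beta relative to its raw coefficient.
#'
#' @inheritParams fit_eb_mixed
#' @return An `eb_mixed_fit` for the standardised model (its
#'   `coefficients` are the standardised betas).
#' @export
standardized_betas <- function(dives, response = "eb_grade") {
  df <- mixed_frame(dives, response)
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  df$y <- zs(df$y); df$depth <- zs(df$depth); df$shallow <- zs(df$shallow)
  fit <- lme4::lmer(y ~ depth + shallow + depth:shallow + (1 | diver_id),
                    data = df, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  mixed_summary(fit, df)
}

#' Intraclass correlation coefficient
#'
#' Between-diver variance over between-diver plus residual variance: the
#' share of unexplained log-grade variance attributable to stable
#' differences between divers.
#'
#' @param tau2 between-diver (random-intercept) variance, `>= 0`.
#' @param sigma2 residual variance, `> 0`.
#' @return `tau2 / (tau2 + sigma2)`.
#' @export
icc <- function(tau2, sigma2) {
  if (tau2 < 0) stop("tau2 must be >= 0", call. = FALSE)
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  tau2 / (tau2 + sigma2)
}

#' Marginal and conditional R-squared of a random-intercept model
#'
#' The marginal R-squared is the variance of the fitted fixed-effect
#' linear predictor over total variance
#' (`Vf / (Vf + tau2 + sigma2)`); the conditional R-squared adds the
#' random-intercept variance to the numerator. With a Gaussian response
#' and identity link there is no distribution-specific variance term.
#' Note the algebraic identity
#' `(R2c - R2m) / (1 - R2m) = tau2 / (tau2 + sigma2)`, i.e. the ICC.
#'
#' @param fixed_effect_variance variance of the fitted fixed-effect
#'   predictor over the data, `>= 0`.
#' @param tau2 between-diver variance, `>= 0`.
#' @param sigma2 residual variance, `>= 0`; the total must be positive.
#' @return Named numeric: `r2_marginal`, `r2_conditional`.
#' @export
nakagawa_r2 <- function(fixed_effect_variance, tau2, sigma2) {
  if (fixed_effect_variance < 0 || tau2 < 0 || sigma2 < 0) {
    stop("variance components must be >= 0", call. = FALSE)
  }
  tot <- fixed_effect_variance + tau2 + sigma2
  if (tot <= 0) stop("total variance must be positive", call. = FALSE)
  c(r2_marginal = fixed_effect_variance / tot,
    r2_conditional = (fixed_effect_variance + tau2) / tot)
}

#' Spearman correlations of candidate predictors with the bubble grade
#'
#' One row per predictor: diver age, BMI, air consumption, total dive
#' time, maximum depth, dive-of-day flag, the four after-maximum-depth
#' band times, total time between 0 and 10 m, and the field-formula
#' prediction. Correlations treat dives as exchangeable (no clustering
#' adjustment); p-values are reported raw by default, with an optional
#' Holm adjustment.
#'
#' @param dives dive-record table with observed grades.
#' @param divers diver table.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A data.frame with columns `variable`, `rho`, `p` (and
#'   `p_adj` when `adjust != "none"`). Constant predictors get `NA`
#'   correlations and a note instead of an error.
#' @export
correlation_table <- function(dives, divers, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  validate_divers(divers)
  m <- merge(dives, divers, by = "diver_id", sort = FALSE)
  m <- m[!is.na(m$eb_grade), ]
  if (nrow(m) < 3L) stop("need at least 3 graded dives", call. = FALSE)
  m$formula_prediction <- predict_eb(m$age_y, m$surface_interval_h,
                                     m$max_depth_m,
                                     m$air_consumption_barl)$predicted_grade
  vars <- c("Age (y)" = "age_y",
            "BMI (kg/m2)" = "bmi",
            "Air consumption (bar L)" = "air_consumption_barl",
            "Total dive time (min)" = "dive_time_min",
            "Maximum depth (m)" = "max_depth_m",
            "First or second dive of the day" = "dive_of_day",
            "Time between 0 and 10 m after max depth (min)" = "am_0_10",
            "Time between 10 and 20 m after max depth (min)" = "am_10_20",
            "Time between 20 and 30 m after max depth (min)" = "am_20_30",
            "Time between 30 and 40 m after max depth (min)" = "am_30_40",
            "Total time between 0 and 10 m (min)" = "t_0_10",
            "Field-formula prediction" = "formula_prediction")
  rows <- lapply(seq_along(vars), function(i) {
    v <- m[[vars[i]]]
    if (length(unique(v)) < 2L) {
      return(data.frame(variable = names(vars)[i], rho = NA_real_,
                        p = NA_real_, note = "constant predictor"))
    }
    rs <- spearman_rho(v, m$eb_grade)
    data.frame(variable = names(vars)[i], rho = rs$rho, p = rs$p, note = "")
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out
}
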