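#' Bagged regression-tree forest
#'
#' A small random-forest regressor (CART trees on bootstrap samples with
#' `mtry` random candidate features per split), used for the
#' variable-set comparison. Implemented in compiled code inside the
#' package so the pipeline has no dependency on an external tree package.
#' Conventional regression defaults: 500 trees, `mtry = max(1, p %/% 3)`,
#' nodes with fewer than 5 cases are not split.
#'
#' @param x numeric matrix or data.frame of predictors (factors must be
#'   encoded numerically beforehand).
#' @param y numeric response.
#' @param ntree number of trees.
#' @param mtry candidate features per split.
#' @param min_split smallest node that may be split.
#' @return An object of class `eb_forest`.
#' @export
eb_forest <- function(x, y, ntree = 500, mtry = max(1L, ncol(x) %/% 3L),
                      min_split = 5L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(y), nrow(x) >= 2L)
  trees <- rf_fit_cpp(x, as.numeric(y), as.integer(ntree),
                      as.integer(mtry), as.integer(min_split))
  structure(list(trees = trees, features = colnames(x), ntree = ntree,
                 mtry = mtry), class = "eb_forest")
}

#' @export
predict.eb_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(newdata) <- "double"
  rf_predict_cpp(object$trees, newdata)
}

#' @export
print.eb_forest <- function(x, ...) {
  cat(sprintf("<eb_forest: %d trees, mtry %d, features: %s>\n",
              x$ntree, x$mtry, paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Predictor sets for the variable-set comparison
#'
#' The six nested predictor sets compared with random forests: person-
#' specific covariates only, minimal dive data, their combinations with
#' and without air consumption, the full dive-computer feature set
#' (depth, time and all eight 10-metre band times), and everything
#' together.
#'
#' @return Named list of character vectors of column names in the merged
#'   dive/diver table (`sex` is encoded 0/1 for the forest).
#' @export
eb_variable_sets <- function() {
  person <- c("age_y", "sex", "bmi")
  minimal <- c("max_depth_m", "dive_time_min")
  bands <- c("t_0_10", "t_10_20", "t_20_30", "t_30_40",
             "am_0_10", "am_10_20", "am_20_30", "am_30_40")
  computer <- c(minimal, bands)
  list(
    person_specific = person,
    minimal_dive = minimal,
    person_dive = c(person, minimal),
    person_dive_air = c(person, minimal, "air_consumption_barl"),
    dive_computer = computer,
    all = unique(c(person, computer, "air_consumption_barl", "dive_of_day"))
  )
}

#' Random-forest comparison of predictor sets
#'
#' For each predictor set, trains a random-forest regressor on a single
#' seeded 70/30 split of the dives and reports the Spearman correlation
#' between predicted and observed grades on the test set, both over all
#' test dives and after excluding test dives with an observed grade of 0.
#' The split is by dive by default; because repeated dives by the same
#' diver are not independent, a diver-blocked split (all of a diver's
#' dives on the same side) is available via `split_by = "diver"`.
#'
#' @param dives dive-record table with observed grades.
#' @param divers diver table.
#' @param sets named list of predictor sets (default [eb_variable_sets()]).
#' @param train_fraction fraction of dives used for training (default 0.7).
#' @param seed integer seed controlling the split and the forests.
#' @param ntree trees per forest.
#' @param split_by `"dive"` (default) or `"diver"`.
#' @param response grade column to predict.
#' @return A data.frame with one row per set: `set`, `rho_all`,
#'   `rho_excluding_zero` (`NA` with a `note` when undefined, e.g.
#'   constant test grades), `n_train`, `n_test`, `seed`.
#' @export
rf_variable_set_eval <- function(dives, divers, sets = eb_variable_sets(),
                                 train_fraction = 0.7, seed = 1L,
                                 ntree = 500, split_by = c("dive", "diver"),
                                 response = "eb_grade") {
  split_by <- match.arg(split_by)
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  validate_divers(divers)
  m <- merge(dives, divers, by = "diver_id", sort = FALSE)
  m <- m[!is.na(m[[response]]), ]
  if (nrow(m) < 10L) stop("need at least 10 graded dives", call. = FALSE)
  m$sex <- as.numeric(m$sex == "M")
  for (s in sets) {
    bad <- setdiff(s, names(m))
    if (length(bad)) stop("unresolvable variables: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(m)
  if (split_by == "dive") {
    train <- sample.int(n) <= round(train_fraction * n)
  } else {
    ids <- unique(m$diver_id)
    tr_ids <- sample(ids, round(train_fraction * length(ids)))
    train <- m$diver_id %in% tr_ids
  }
  if (sum(train) < 5L || sum(!train) < 3L) {
    stop("degenerate train/test split", call. = FALSE)
  }
  y <- m[[response]]
  safe_rho <- function(pred, obs) {
    tryCatch(spearman_rho(pred, obs)$rho, error = function(e) NA_real_)
  }
  rows <- lapply(names(sets), function(nm) {
    fml <- sets[[nm]]
    fit <- eb_forest(m[train, fml, drop = FALSE], y[train], ntree = ntree)
    pred <- predict(fit, m[!train, fml, drop = FALSE])
    obs <- y[!train]
    rho_all <- safe_rho(pred, obs)
    nz <- obs >= 1
    rho_nz <- if (sum(nz) >= 3L) safe_rho(pred[nz], obs[nz]) else NA_real_
    data.frame(set = nm, rho_all = rho_all, rho_excluding_zero = rho_nz,
               n_train = sum(train), n_test = sum(!train), seed = seed,
               note = if (anyNA(c(rho_all, rho_nz)))
                 "undefined correlation (constant or too few values)" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
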