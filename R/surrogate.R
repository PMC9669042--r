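RESPONSE_COL <- "urine_osm"
ID_COLS <- c("participant_id", "visit_index")
RANGER_SENTINEL <- -1e6  # missing-as-sentinel encoding for learners without NA routing

#' Default candidate feature columns of a cohort table
#' @param rows a cohort data.frame.
#' @return character vector of candidate feature names (everything except
#'   identifiers and the response).
#' @export
candidate_features <- function(rows) {
  setdiff(names(rows), c(ID_COLS, RESPONSE_COL))
}

# numeric design matrix; sex coded female=1/male=0; NA preserved unless a
# sentinel is requested
encode_features <- function(rows, features, sentinel = NULL) {
  rows <- as.data.frame(rows)
  miss <- setdiff(features, names(rows))
  if (length(miss)) stop("rows lack feature columns: ", paste(miss, collapse = ", "))
  cols <- lapply(features, function(f) {
    v <- rows[[f]]
    if (f == "sex" || is.character(v) || is.factor(v)) {
      v <- as.character(v)
      out <- ifelse(v == "female", 1, ifelse(v == "male", 0, NA_real_))
    } else out <- as.numeric(v)
    out
  })
  m <- do.call(cbind, cols)
  colnames(m) <- features
  if (!is.null(sentinel)) m[is.na(m)] <- sentinel
  m
}

#' Rank candidate features by fractional split gain
#'
#' Fits a gradient-boosted tree ensemble on the training rows and reports
#' each feature's share of the total split gain (dimensionless, summing to
#' one over all candidates; features used in no split score zero). A
#' max-normalized column is included for display parity with importance
#' plots scaled to the top feature.
#'
#' @param train_rows training records including the `urine_osm` response.
#' @param features candidate feature names (default: all non-ID columns).
#' @param seed integer seed.
#' @param nrounds,max_depth,eta booster settings for the ranking model.
#' @return A `feature_importance` data.frame with columns `feature`,
#'   `fractional_gain`, `max_normalized`, `rank`.
#' @export
rank_features <- function(train_rows, features = candidate_features(train_rows),
                          seed = 1L, nrounds = 200, max_depth = 6, eta = 0.1) {
  train_rows <- as.data.frame(train_rows)
  if (length(features) < 2L) stop("need at least 2 candidate features")
  if (nrow(train_rows) < 20L) stop("need at least 20 training rows")
  y <- train_rows[[RESPONSE_COL]]
  if (anyNA(y)) stop("response contains missing values")
  if (sd(y) == 0) stop("degenerate response: urine_osm is constant")
  x <- encode_features(train_rows, features)
  booster <- withr::with_seed(as.integer(seed), {
    xgboost::xgb.train(
      params = list(max_depth = max_depth, eta = eta, nthread = 1,
                    objective = "reg:squarederror", subsample = 1),
      data = xgboost::xgb.DMatrix(x, label = y), nrounds = nrounds, verbose = 0)
  })
  imp <- xgboost::xgb.importance(model = booster)
  gain <- setNames(rep(0, length(features)), features)
  gain[imp$Feature] <- imp$Gain
  gain <- gain / sum(gain)
  ord <- order(-gain, names(gain))
  out <- data.frame(feature = names(gain)[ord],
                    fractional_gain = unname(gain[ord]),
                    max_normalized = unname(gain[ord] / max(gain)),
                    row.names = NULL)
  out$rank <- seq_len(nrow(out))
  class(out) <- c("feature_importance", "data.frame")
  out
}

#' Feature policy: which features may enter the deployable model
#'
#' Urine-derived features (24 h urine volume, number of micturitions) are
#' highly predictive of urine osmolality but not accessible outside a
#' clinical context, so they are excluded from the deployable feature set
#' by default. The response and participant identifier are never allowed.
#'
#' @param excluded_features names to forbid (default the urine features).
#' @param allowed_features the final modelling list, or `NULL` to allow all
#'   remaining candidates.
#' @return A `feature_policy` object.
#' @export
feature_policy <- function(excluded_features = c("urine_volume", "n_micturitions"),
                           allowed_features = NULL) {
  forbidden <- c(RESPONSE_COL, "participant_id")
  if (!is.null(allowed_features)) {
    bad <- intersect(allowed_features, c(excluded_features, forbidden))
    if (length(bad))
      stop("allowed_features contains excluded/forbidden names: ",
           paste(bad, collapse = ", "))
  }
  structure(list(excluded_features = excluded_features,
                 allowed_features = allowed_features),
            class = "feature_policy")
}

#' Prune a candidate feature list under a policy
#'
#' @param importances a `feature_importance` table (or character vector of
#'   candidate names).
#' @param policy a [feature_policy()].
#' @return character vector: the final modelling features, order preserved.
#' @export
prune_features <- function(importances, policy = feature_policy()) {
  if (!inherits(policy, "feature_policy")) stop("`policy` must be feature_policy()")
  candidates <- if (inherits(importances, "data.frame")) importances$feature
                else as.character(importances)
  keep <- if (is.null(policy$allowed_features)) candidates
          else policy$allowed_features[policy$allowed_features %in% candidates]
  keep <- setdiff(keep, c(policy$excluded_features, RESPONSE_COL, "participant_id"))
  if (!length(keep)) stop("no features remain after applying the policy")
  keep
}

#' Mean absolute error
#'
#' `MAE = (1/N) * sum(|y_i - yhat_i|)`: same scale as the response, robust
#' to infrequent large errors.
#'
#' @param actual,predicted numeric vectors of equal length (no missing).
#' @return The mean absolute error.
#' @export
mae <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) < 1L) stop("need at least one observation")
  if (anyNA(actual) || anyNA(predicted)) stop("missing values not allowed")
  mean(abs(actual - predicted))
}

#' Hyperparameter search space
#'
#' Box bounds for seeded random search: tree depth 3-8, learning rate
#' 0.03-0.3 (log-uniform), 100-600 boosting rounds, row subsample 0.7-1.0.
#' The random-forest comparator draws trees 200-600, mtry and minimum node
#' size from analogous ranges.
#'
#' @return list of bounds used by [fit_surrogate()].
#' @export
surrogate_search_space <- function() {
  list(max_depth = c(3L, 8L), eta = c(0.03, 0.3), nrounds = c(100L, 600L),
       subsample = c(0.7, 1.0),
       num_trees = c(200L, 600L), min_node_size = c(2L, 20L))
}

# participant-grouped fold assignment: no participant straddles folds
grouped_folds <- function(ids, k, seed) {
  uid <- sort(unique(as.character(ids)))
  if (length(uid) < k) k <- max(2L, length(uid))
  shuffled <- withr::with_seed(as.integer(seed), sample(uid))
  fold_of <- setNames(rep(seq_len(k), length.out = length(uid)), shuffled)
  unname(fold_of[as.character(ids)])
}

draw_params <- function(learner, space, n_features) {
  if (learner == "xgboost") {
    list(max_depth = sample(space$max_depth[1]:space$max_depth[2], 1),
         eta = exp(runif(1, log(space$eta[1]), log(space$eta[2]))),
         nrounds = sample(seq(space$nrounds[1], space$nrounds[2], by = 50), 1),
         subsample = runif(1, space$subsample[1], space$subsample[2]))
  } else {
    list(num_trees = sample(seq(space$num_trees[1], space$num_trees[2], by = 100), 1),
         mtry = sample(seq_len(max(2L, n_features - 1L)), 1),
         min_node_size = sample(space$min_node_size[1]:space$min_node_size[2], 1))
  }
}

fit_one <- function(learner, x, y, pars, seed) {
  if (learner == "xgboost") {
    withr::with_seed(seed, xgboost::xgb.train(
      params = list(max_depth = pars$max_depth, eta = pars$eta,
                    subsample = pars$subsample, nthread = 1,
                    objective = "reg:squarederror"),
      data = xgboost::xgb.DMatrix(x, label = y),
      nrounds = pars$nrounds, verbose = 0))
  } else {
    df <- as.data.frame(x)
    df$.y <- y
    ranger::ranger(dependent.variable.name = ".y", data = df,
                   num.trees = pars$num_trees,
                   mtry = min(pars$mtry, ncol(x)),
                   min.node.size = pars$min_node_size,
                   num.threads = 1, seed = seed)
  }
}

predict_one <- function(learner, fit, x) {
  if (learner == "xgboost") predict(fit, xgboost::xgb.DMatrix(x))
  else predict(fit, data = as.data.frame(x))$predictions
}

#' Fit a surrogate model for urine osmolality
#'
#' Tunes hyperparameters by seeded random search with participant-grouped
#' k-fold cross-validation (no participant appears in both a training fold
#' and its validation fold), selects the draw with the lowest mean CV MAE,
#' and refits on the full training set. The boosted-tree learner routes
#' missing values natively; the random-forest comparator receives a
#' missing-as-sentinel encoding (documented constant far outside the data
#' range), so both yield finite predictions on records with missing intake.
#'
#' Feature columns that are entirely missing are dropped with a warning.
#'
#' @param train_rows training records including `urine_osm` and
#'   `participant_id`.
#' @param features modelling feature names.
#' @param learner `"xgboost"` (gradient-boosted trees, primary) or
#'   `"ranger"` (random forest comparator).
#' @param search space from [surrogate_search_space()].
#' @param n_search number of random draws (default 50).
#' @param cv_folds folds for grouped CV (default 5).
#' @param seed integer seed; drives folds, draws and fits.
#' @return A `surrogate_model` with the fitted booster, the feature list,
#'   chosen hyperparameters, the CV table and the training MAE.
#' @export
fit_surrogate <- function(train_rows, features,
                          learner = c("xgboost", "ranger"),
                          search = surrogate_search_space(),
                          n_search = 50, cv_folds = 5, seed = 1L) {
  learner <- match.arg(learner)
  train_rows <- as.data.frame(train_rows)
  if (cv_folds < 2L) stop("`cv_folds` must be >= 2")
  y <- train_rows[[RESPONSE_COL]]
  if (is.null(y) || anyNA(y)) stop("training rows need a complete `urine_osm` response")
  sentinel <- if (learner == "ranger") RANGER_SENTINEL else NULL
  x <- encode_features(train_rows, features, sentinel = NULL)
  all_na <- colnames(x)[colSums(!is.na(x)) == 0L]
  if (length(all_na)) {
    warning("dropping all-missing feature columns: ", paste(all_na, collapse = ", "))
    features <- setdiff(features, all_na)
    x <- x[, features, drop = FALSE]
  }
  if (!is.null(sentinel)) x[is.na(x)] <- sentinel
  folds <- grouped_folds(train_rows$participant_id %||% seq_len(nrow(train_rows)),
                         cv_folds, seed)
  draws <- withr::with_seed(as.integer(seed) + 1L,
                            lapply(seq_len(n_search), function(i)
                              draw_params(learner, search, length(features))))
  cv_mae <- vapply(seq_along(draws), function(i) {
    pars <- draws[[i]]
    errs <- vapply(sort(unique(folds)), function(k) {
      tr <- folds != k
      fit <- fit_one(learner, x[tr, , drop = FALSE], y[tr], pars,
                     child_seed(seed, i))
      mae(y[!tr], predict_one(learner, fit, x[!tr, , drop = FALSE]))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- which.min(cv_mae)
  fit <- fit_one(learner, x, y, draws[[best]], child_seed(seed, 0L))
  train_pred <- predict_one(learner, fit, x)
  structure(list(
    learner_kind = learner,
    fit = fit,
    features = features,
    hyperparameters = draws[[best]],
    cv = data.frame(draw = seq_along(cv_mae), cv_mae = cv_mae),
    cv_folds = cv_folds,
    training_mae = mae(y, train_pred),
    sentinel = sentinel,
    seed = as.integer(seed)
  ), class = "surrogate_model")
}

#' Predict urine osmolality from a fitted surrogate
#'
#' @param object a `surrogate_model`.
#' @param newdata records carrying the model's feature columns; missing
#'   entries are allowed and routed by the learner.
#' @param ... unused.
#' @return numeric vector of predicted urine osmolality (mOsm/kg).
#' @export
predict.surrogate_model <- function(object, newdata, ...) {
  x <- encode_features(as.data.frame(newdata), object$features,
                       sentinel = object$sentinel)
  p <- predict_one(object$learner_kind, object$fit, x)
  stopifnot(all(is.finite(p)))
  p
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("Surrogate model (%s), %d features\n",
              x$learner_kind, length(x$features)))
  cat(sprintf("  grouped %d-fold CV over %d draws; best CV MAE %.2f mOsm/kg\n",
              x$cv_folds, nrow(x$cv), min(x$cv$cv_mae)))
  cat(sprintf("  training MAE %.2f mOsm/kg\n", x$training_mae))
  invisible(x)
}

#' Compare learners with repeated train/test cycles
#'
#' Repeats the whole participant split + tune + fit + test-MAE cycle
#' `n_repeats` times with distinct split seeds, tuning every learner under
#' the same folds and seed discipline, and summarizes per-learner MAE mean
#' and SD (the repeat-stability assessment).
#'
#' @param rows filtered cohort rows.
#' @param learner_kinds character vector of learners (>= 1).
#' @param features modelling feature list.
#' @param ratio train proportion, default 0.75.
#' @param n_repeats full split+fit cycles, default 5.
#' @param seed base seed; repeat r uses `seed + r`.
#' @inheritParams fit_surrogate
#' @return A `stability_report`: `mae` (learner x repeat matrix),
#'   `summary` data.frame (mean, sd per learner; sd `NA` with
#'   `sd_undefined = TRUE` when `n_repeats = 1`).
#' @export
compare_learners <- function(rows, learner_kinds = c("xgboost", "ranger"),
                             features, ratio = 0.75, n_repeats = 5,
                             search = surrogate_search_space(),
                             n_search = 50, cv_folds = 5, seed = 1L) {
  if (length(learner_kinds) < 1L) stop("need at least one learner kind")
  m <- matrix(NA_real_, length(learner_kinds), n_repeats,
              dimnames = list(learner_kinds, NULL))
  for (r in seq_len(n_repeats)) {
    sp <- split_by_participant(rows, ratio, seed = as.integer(seed) + r)
    for (lk in learner_kinds) {
      mod <- fit_surrogate(sp$train, features, learner = lk, search = search,
                           n_search = n_search, cv_folds = cv_folds,
                           seed = as.integer(seed) + r)
      m[lk, r] <- mae(sp$test[[RESPONSE_COL]], predict(mod, sp$test))
    }
  }
  summ <- data.frame(learner = learner_kinds,
                     mean_mae = rowMeans(m),
                     sd_mae = apply(m, 1, function(v) if (n_repeats > 1) sd(v) else NA_real_),
                     row.names = NULL)
  structure(list(mae = m, summary = summ, n_repeats = n_repeats,
                 sd_undefined = n_repeats == 1L),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Learner comparison over %d repeated splits (test MAE, mOsm/kg)\n",
              x$n_repeats))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
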