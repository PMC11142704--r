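#' Hyperparameters of one gradient-boosting model
#'
#' @param learning_rate shrinkage per boosting round.
#' @param max_tree_depth maximum tree depth.
#' @param lambda_reg,alpha_reg L2 / L1 regularization.
#' @param max_delta_step maximum delta step per leaf.
#' @param min_child_weight minimum child weight.
#' @param num_rounds number of boosting rounds.
#' @param negative_class_weight training weight assigned to negative
#'   records (classification only; < 1 down-weights the over-represented
#'   negative class).
#' @return a `gbm_hyperparams` list.
#' @export
gbm_hyperparams <- function(learning_rate = 0.1, max_tree_depth = 6L,
                            lambda_reg = 1, alpha_reg = 0,
                            max_delta_step = 0, min_child_weight = 1,
                            num_rounds = 100L, negative_class_weight = 1) {
  out <- list(learning_rate = learning_rate,
              max_tree_depth = as.integer(max_tree_depth),
              lambda_reg = lambda_reg, alpha_reg = alpha_reg,
              max_delta_step = max_delta_step,
              min_child_weight = min_child_weight,
              num_rounds = as.integer(num_rounds),
              negative_class_weight = negative_class_weight)
  for (nm in names(out)) assert_scalar_number(out[[nm]], nm)
  if (out$learning_rate <= 0 || out$num_rounds < 1 || out$max_tree_depth < 1)
    ps_abort("invalid gbm hyperparameters", "psinter_value_error")
  structure(out, class = "gbm_hyperparams")
}

#' Random-search space for GBM hyperparameters
#'
#' Each field is sampled independently: log-uniform fields on the log10
#' scale, uniform fields linearly, integer fields as uniform integers.
#' The `"default"` preset spans the wide ranges appropriate for full-scale
#' runs; `"compact"` narrows the ranges (notably `num_rounds` <= 150) for
#' desk-scale experiments where thousands of deep-tree fits are not
#' warranted by a few thousand training rows.
#'
#' @param preset `"default"` or `"compact"`.
#' @return a named list of range specifications (class `gbm_search_space`);
#'   fields may be replaced before use. Each element is
#'   `list(min =, max =, scale = "linear"|"log", integer = TRUE/FALSE)`.
#' @export
gbm_search_space <- function(preset = c("default", "compact")) {
  preset <- match.arg(preset)
  rng <- function(min, max, scale = "linear", integer = FALSE)
    list(min = min, max = max, scale = scale, integer = integer)
  space <- if (preset == "default") list(
    learning_rate = rng(1e-3, 0.5, "log"),
    max_tree_depth = rng(2, 14, integer = TRUE),
    lambda_reg = rng(1e-4, 1e2, "log"),
    alpha_reg = rng(1e-4, 1e2, "log"),
    max_delta_step = rng(0, 10),
    min_child_weight = rng(0.1, 100, "log"),
    num_rounds = rng(20, 2000, integer = TRUE),
    negative_class_weight = rng(0.1, 1)
  ) else list(
    learning_rate = rng(0.03, 0.3, "log"),
    max_tree_depth = rng(2, 7, integer = TRUE),
    lambda_reg = rng(1e-3, 10, "log"),
    alpha_reg = rng(1e-4, 1, "log"),
    max_delta_step = rng(0, 5),
    min_child_weight = rng(0.5, 20, "log"),
    num_rounds = rng(20, 150, integer = TRUE),
    negative_class_weight = rng(0.1, 1)
  )
  structure(space, class = "gbm_search_space")
}

sample_hyperparams <- function(space) {
  vals <- lapply(space, function(r) {
    if (is.null(r$min) || is.null(r$max) || r$max < r$min)
      ps_abort("degenerate search space range", "psinter_space_error")
    if (isTRUE(r$integer))
      return(min(r$max, floor(stats::runif(1, r$min, r$max + 1))))
    if (identical(r$scale, "log")) {
      10^stats::runif(1, log10(r$min), log10(r$max))
    } else stats::runif(1, r$min, r$max)
  })
  do.call(gbm_hyperparams, vals)
}

hp_to_xgb_params <- function(hp, task, nthread = 1L, seed = 0L) {
  list(eta = hp$learning_rate, max_depth = hp$max_tree_depth,
       lambda = hp$lambda_reg, alpha = hp$alpha_reg,
       max_delta_step = hp$max_delta_step,
       min_child_weight = hp$min_child_weight,
       objective = if (task == "binary_classification") "binary:logistic"
                   else "reg:squarederror",
       tree_method = "hist", nthread = nthread, seed = seed)
}

#' Train one gradient-boosting model
#'
#' Fits a boosted decision-tree model (XGBoost backend) on a feature
#' matrix. Deterministic for a fixed `seed` (single-threaded).
#'
#' @param features numeric feature matrix.
#' @param labels numeric labels (0/1 for classification).
#' @param hp a [gbm_hyperparams()].
#' @param task `"regression"` or `"binary_classification"`.
#' @param seed RNG seed passed to the tree builder.
#' @return a `gbm_model`: list with the fitted booster, feature width,
#'   task, and hyperparameters.
#' @export
train_gbm <- function(features, labels, hp = gbm_hyperparams(),
                      task = c("regression", "binary_classification"),
                      seed = 1L) {
  task <- match.arg(task)
  if (nrow(features) != length(labels))
    ps_abort("feature rows and labels must align", "psinter_shape_error")
  weight <- if (task == "binary_classification") {
    ifelse(labels == 0, hp$negative_class_weight, 1)
  } else rep(1, length(labels))
  dtrain <- xgboost::xgb.DMatrix(as.matrix(features), label = labels,
                                 weight = weight, nthread = 1)
  booster <- xgboost::xgb.train(
    params = hp_to_xgb_params(hp, task, seed = as.integer(seed)),
    data = dtrain, nrounds = hp$num_rounds, verbose = 0)
  structure(list(booster = booster, width = ncol(features), task = task,
                 hyperparams = hp, seed = as.integer(seed)),
            class = "gbm_model")
}

#' @export
predict.gbm_model <- function(object, newdata, ...) {
  if (ncol(newdata) != object$width)
    ps_abort(sprintf("feature width %d does not match the model (%d)",
                     ncol(newdata), object$width), "psinter_shape_error")
  predict(object$booster, xgboost::xgb.DMatrix(as.matrix(newdata), nthread = 1))
}

#' Random hyperparameter search for one GBM
#'
#' Pure independent random sampling: each trial draws every field of the
#' search space independently, trains on the training features and is
#' scored on the validation features (validation MSE minimized for
#' regression; validation MCC maximized for classification). Returns the
#' best configuration and the full trials log.
#'
#' @param train_features,train_labels training data.
#' @param val_features,val_labels validation data.
#' @param task `"regression"` or `"binary_classification"`.
#' @param space a [gbm_search_space()].
#' @param n_iter number of random trials (2000 at full scale).
#' @param seed RNG seed for sampling and tree fitting.
#' @return list with `best_hp` ([gbm_hyperparams()]), `best_score`,
#'   and `trials` (data frame: trial index, every hyperparameter, score).
#' @export
random_search <- function(train_features, train_labels, val_features,
                          val_labels,
                          task = c("regression", "binary_classification"),
                          space = gbm_search_space(), n_iter = 2000L,
                          seed = 1L) {
  task <- match.arg(task)
  if (n_iter < 1L) ps_abort("n_iter must be >= 1", "psinter_value_error")
  if (!length(space)) ps_abort("empty search space", "psinter_space_error")
  trials <- vector("list", n_iter)
  best <- list(score = -Inf, hp = NULL)
  with_seed(derive_seed("random_search", seed), {
    for (i in seq_len(n_iter)) {
      hp <- sample_hyperparams(space)
      model <- train_gbm(train_features, train_labels, hp, task, seed = seed)
      p <- predict(model, val_features)
      score <- if (task == "regression") {
        -mean((val_labels - p)^2)            # maximize -MSE
      } else {
        tryCatch(binary_metrics(val_labels, p)$mcc, psinter_error = function(e) -Inf)
      }
      trials[[i]] <- c(trial = i, unlist(hp), score = score)
      if (score > best$score) best <- list(score = score, hp = hp)
    }
  })
  trials <- as.data.frame(do.call(rbind, trials))
  list(best_hp = best$hp,
       best_score = if (task == "regression") -best$score else best$score,
       trials = trials)
}

#' Fit ensemble weights on the probability simplex
#'
#' Exhaustive search over the simplex grid with step 0.05 (231 candidate
#' weight triples) for the convex combination of the three model
#' prediction vectors that minimizes validation MSE (regression) or
#' maximizes validation MCC (classification). Ties are broken toward the
#' earliest grid point in lexicographic (w1, w2, w3) order.
#'
#' @param val_preds list of three prediction vectors (cls_only,
#'   pooled_pair, all).
#' @param val_labels validation labels.
#' @param task `"regression"` or `"binary_classification"`.
#' @param step grid step on the simplex.
#' @return numeric weight vector `c(w1, w2, w3)`, non-negative, summing
#'   to 1.
#' @export
fit_ensemble_weights <- function(val_preds, val_labels,
                                 task = c("regression", "binary_classification"),
                                 step = 0.05) {
  task <- match.arg(task)
  if (length(val_preds) != 3L)
    ps_abort("val_preds must contain three prediction vectors",
             "psinter_value_error")
  lens <- vapply(val_preds, length, integer(1))
  if (any(lens != length(val_labels)))
    ps_abort("prediction vectors and labels must have equal length",
             "psinter_shape_error")
  P <- cbind(val_preds[[1]], val_preds[[2]], val_preds[[3]])
  grid1 <- seq(0, 1, by = step)
  best <- list(score = -Inf, w = NULL)
  for (w1 in grid1) {
    for (w2 in grid1) {
      w3 <- 1 - w1 - w2
      if (w3 < -1e-12) next
      w3 <- max(w3, 0)
      pred <- as.numeric(P %*% c(w1, w2, w3))
      score <- if (task == "regression") {
        -mean((val_labels - pred)^2)
      } else {
        tryCatch(binary_metrics(val_labels, pred)$mcc,
                 psinter_error = function(e) -Inf)
      }
      if (score > best$score + 1e-15) best <- list(score = score, w = c(w1, w2, w3))
    }
  }
  best$w
}

#' Weighted-mean ensemble prediction
#'
#' @param model an `ensemble_model` (see [finalize_models()]), or any list
#'   with elements `models` (three `gbm_model`s) and `weights`.
#' @param features named list of feature matrices, one per variant
#'   (`cls_only`, `pooled_pair`, `all`).
#' @return numeric prediction vector `w1*p1 + w2*p2 + w3*p3`.
#' @export
ensemble_predict <- function(model, features) {
  missing <- setdiff(FEATURE_VARIANTS, names(features))
  if (length(missing))
    ps_abort(sprintf("missing features for variant(s): %s",
                     paste(missing, collapse = ", ")), "psinter_value_error")
  preds <- lapply(FEATURE_VARIANTS,
                  function(v) predict(model$models[[v]], features[[v]]))
  as.numeric(cbind(preds[[1]], preds[[2]], preds[[3]]) %*% model$weights)
}

#' Retrain finalist models on train + validation
#'
#' After hyperparameter selection, each of the three models is retrained
#' with its chosen hyperparameters on the union of training and
#' validation data; the validation-fitted ensemble weights are carried
#' over unchanged. Optionally audits that no test record leaks into the
#' final training data.
#'
#' @param train_features,val_features named lists of feature matrices per
#'   variant.
#' @param train_labels,val_labels label vectors.
#' @param best_hp named list of [gbm_hyperparams()] per variant.
#' @param weights ensemble weight vector from [fit_ensemble_weights()].
#' @param task task kind.
#' @param seed RNG seed for the tree builder.
#' @param train_keys,val_keys,test_keys optional record keys; when test
#'   keys are supplied, any overlap with train/val keys raises a leakage
#'   error.
#' @return an `ensemble_model`: list with `models` (per variant),
#'   `weights`, `hyperparams`, `task`.
#' @export
finalize_models <- function(train_features, val_features, train_labels,
                            val_labels, best_hp, weights,
                            task = c("regression", "binary_classification"),
                            seed = 1L, train_keys = NULL, val_keys = NULL,
                            test_keys = NULL) {
  task <- match.arg(task)
  if (!is.null(test_keys)) {
    leaked <- intersect(c(train_keys, val_keys), test_keys)
    if (length(leaked))
      ps_abort(sprintf("test record(s) leaked into training data: %s",
                       paste(utils::head(leaked, 3L), collapse = ", ")),
               "psinter_leakage_error", keys = leaked)
  }
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0))
    ps_abort("weights must be non-negative and sum to 1", "psinter_value_error")
  models <- lapply(FEATURE_VARIANTS, function(v) {
    train_gbm(rbind(train_features[[v]], val_features[[v]]),
              c(train_labels, val_labels), best_hp[[v]], task, seed = seed)
  })
  names(models) <- FEATURE_VARIANTS
  structure(list(models = models, weights = weights, hyperparams = best_hp,
                 task = task),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> task: %s  weights: (%.2f, %.2f, %.2f)\n",
              x$task, x$weights[1], x$weights[2], x$weights[3]))
  invisible(x)
}
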