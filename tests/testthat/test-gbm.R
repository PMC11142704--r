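linear_features <- function(n, d, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  list(X = X, y = X[, 1] - 0.5 * X[, 2] + rnorm(n, sd = 0.1))
}

test_that("boosted models fit signal and are deterministic", {
  lf <- linear_features(200, 6, seed = 1)
  hp <- gbm_hyperparams(num_rounds = 60L)
  m <- train_gbm(lf$X, lf$y, hp, "regression", seed = 3L)
  p <- predict(m, lf$X)
  expect_lt(mean((lf$y - p)^2), var(lf$y))
  m2 <- train_gbm(lf$X, lf$y, hp, "regression", seed = 3L)
  expect_identical(p, predict(m2, lf$X))
  expect_error(predict(m, lf$X[, 1:3]), class = "psinter_shape_error")
})

test_that("a depth-1 single-round model is a decision stump", {
  lf <- linear_features(150, 4, seed = 2)
  m <- train_gbm(lf$X, lf$y, gbm_hyperparams(num_rounds = 1L,
                                             max_tree_depth = 1L),
                 "regression", seed = 1L)
  expect_lte(length(unique(predict(m, lf$X))), 2L)
})

test_that("random search scans the space reproducibly", {
  lf <- linear_features(120, 4, seed = 3)
  val <- linear_features(60, 4, seed = 4)
  space <- gbm_search_space("compact")
  rs1 <- random_search(lf$X, lf$y, val$X, val$y, task = "regression",
                       space = space, n_iter = 8L, seed = 5L)
  rs2 <- random_search(lf$X, lf$y, val$X, val$y, task = "regression",
                       space = space, n_iter = 8L, seed = 5L)
  expect_identical(rs1$trials, rs2$trials)
  expect_equal(nrow(rs1$trials), 8L)
  # returned configuration achieves the best logged score
  expect_equal(-rs1$best_score, max(rs1$trials$score))
  expect_equal(rs1$best_score, min(-rs1$trials$score))

  # single-point space returns that point
  point <- lapply(list(learning_rate = 0.1, max_tree_depth = 3,
                       lambda_reg = 1, alpha_reg = 0.001,
                       max_delta_step = 0, min_child_weight = 1,
                       num_rounds = 25, negative_class_weight = 1),
                  function(v) list(min = v, max = v, scale = "linear",
                                   integer = v == round(v) && v >= 1))
  rs3 <- random_search(lf$X, lf$y, val$X, val$y, task = "regression",
                       space = structure(point, class = "gbm_search_space"),
                       n_iter = 3L, seed = 1L)
  expect_equal(rs3$best_hp$learning_rate, 0.1)
  expect_equal(rs3$best_hp$num_rounds, 25L)

  bad <- space; bad$learning_rate$max <- bad$learning_rate$min / 2
  expect_error(random_search(lf$X, lf$y, val$X, val$y, space = bad,
                             n_iter = 2L, seed = 1L),
               class = "psinter_space_error")
})

test_that("simplex weights recover a perfect model and break ties first", {
  set.seed(6)
  y <- rnorm(50)
  preds <- list(y, rnorm(50), rnorm(50))
  expect_equal(fit_ensemble_weights(preds, y, "regression"), c(1, 0, 0))
  # all-identical predictions: earliest lexicographic grid point
  same <- list(preds[[2]], preds[[2]], preds[[2]])
  w <- fit_ensemble_weights(same, y, "regression")
  expect_equal(w, c(0, 0, 1))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_error(fit_ensemble_weights(list(y, y, y[-1]), y, "regression"),
               class = "psinter_shape_error")
})

test_that("ensemble predictions are the stated convex combinations", {
  lf <- linear_features(100, 3, seed = 8)
  models <- lapply(1:3, function(i)
    train_gbm(lf$X, lf$y + i, gbm_hyperparams(num_rounds = 10L),
              "regression", seed = i))
  names(models) <- c("cls_only", "pooled_pair", "all")
  feats <- list(cls_only = lf$X, pooled_pair = lf$X, all = lf$X)
  em <- list(models = models, weights = c(1, 0, 0))
  expect_identical(ensemble_predict(em, feats),
                   predict(models$cls_only, lf$X))
  em$weights <- c(1, 1, 1) / 3
  p <- ensemble_predict(em, feats)
  manual <- (predict(models$cls_only, lf$X) +
               predict(models$pooled_pair, lf$X) +
               predict(models$all, lf$X)) / 3
  expect_equal(p, manual)
  expect_equal(sum(c(0.5, 0.25, 0.25) * c(4, 0, 8)), 4)
  expect_error(ensemble_predict(em, feats[c("cls_only", "all")]),
               class = "psinter_value_error")
})

test_that("grid-optimal ensemble is no worse than any vertex model", {
  set.seed(9)
  y <- rnorm(80)
  preds <- list(y + rnorm(80, sd = 0.5), y + rnorm(80, sd = 0.8),
                y + rnorm(80, sd = 0.3))
  w <- fit_ensemble_weights(preds, y, "regression")
  mse <- function(p) mean((y - p)^2)
  ens <- mse(preds[[1]] * w[1] + preds[[2]] * w[2] + preds[[3]] * w[3])
  for (p in preds) expect_lte(ens, mse(p) + 1e-12)
})

test_that("finalize retrains on the union and audits leakage", {
  lf <- linear_features(120, 4, seed = 10)
  tr <- 1:80; va <- 81:120
  hp <- list(cls_only = gbm_hyperparams(num_rounds = 15L),
             pooled_pair = gbm_hyperparams(num_rounds = 15L),
             all = gbm_hyperparams(num_rounds = 15L))
  trf <- list(cls_only = lf$X[tr, ], pooled_pair = lf$X[tr, ], all = lf$X[tr, ])
  vaf <- list(cls_only = lf$X[va, ], pooled_pair = lf$X[va, ], all = lf$X[va, ])
  w <- c(0.4, 0.35, 0.25)
  em <- finalize_models(trf, vaf, lf$y[tr], lf$y[va], hp, w, "regression",
                        seed = 1L, train_keys = tr, val_keys = va,
                        test_keys = 200:220)
  expect_s3_class(em, "ensemble_model")
  expect_identical(em$weights, w)
  expect_length(predict(em$models$cls_only, lf$X[1:3, ]), 3L)
  expect_error(
    finalize_models(trf, vaf, lf$y[tr], lf$y[va], hp, w, "regression",
                    train_keys = tr, val_keys = va, test_keys = c(80, 300)),
    class = "psinter_leakage_error")
})

test_that("classification ensembles stay inside [0, 1]", {
  set.seed(12)
  X <- matrix(rnorm(300), 100, 3)
  y <- as.numeric(X[, 1] + rnorm(100, sd = 0.5) > 0)
  models <- lapply(1:3, function(i)
    train_gbm(X, y, gbm_hyperparams(num_rounds = 20L,
                                    negative_class_weight = 0.8),
              "binary_classification", seed = i))
  names(models) <- c("cls_only", "pooled_pair", "all")
  em <- list(models = models, weights = c(0.2, 0.5, 0.3))
  p <- ensemble_predict(em, list(cls_only = X, pooled_pair = X, all = X))
  expect_true(all(p >= 0 & p <= 1))
})
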