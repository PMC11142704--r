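# Independent brute-force oracles used throughout this file. They are
# deliberately naive: O(n^2) pair enumeration and direct textbook
# formulas, kept free of any shared code with the implementations.

oracle_ci <- function(y, yhat) {
  num <- 0; den <- 0
  for (i in seq_along(y)) for (j in seq_along(y)) {
    if (j <= i || y[i] == y[j]) next
    den <- den + 1
    hi <- if (y[i] > y[j]) i else j; lo <- if (y[i] > y[j]) j else i
    if (yhat[hi] > yhat[lo]) num <- num + 1
    else if (yhat[hi] == yhat[lo]) num <- num + 0.5
  }
  num / den
}

oracle_rm2 <- function(y, yhat) {
  r2 <- (sum((y - mean(y)) * (yhat - mean(yhat))) /
           sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2)))^2
  k <- sum(y * yhat) / sum(yhat^2)
  r02 <- 1 - sum((y - k * yhat)^2) / sum((y - mean(y))^2)
  r2 * (1 - sqrt(max(r2 - r02, 0)))
}

oracle_auc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

test_that("regression metrics match their definitions", {
  y <- c(0, 1); yhat <- c(1, 0)
  m <- regression_metrics(y, yhat)
  expect_equal(m$mse, 1)
  expect_equal(m$r_squared, -3)   # SSres = 2, SStot = 0.5

  set.seed(1)
  y2 <- rnorm(40); p2 <- y2 + rnorm(40, sd = 0.3)
  m2 <- regression_metrics(y2, p2)
  expect_equal(m2$r_squared, 1 - sum((y2 - p2)^2) / sum((y2 - mean(y2))^2))
  expect_equal(m2$pearson_r, cor(y2, p2))

  perfect <- regression_metrics(y2, y2)
  expect_equal(unlist(perfect), c(mse = 0, r_squared = 1, pearson_r = 1))

  expect_error(regression_metrics(y2, rep(mean(y2), 40)),
               class = "psinter_metric_undefined")
  expect_error(regression_metrics(rep(1, 5), rnorm(5)),
               class = "psinter_metric_undefined")
})

test_that("concordance index handles ties per the standard convention", {
  expect_equal(concordance_index(c(1, 2, 3), c(0.1, 0.3, 0.2)), 2 / 3)
  expect_equal(concordance_index(c(1, 1, 2), c(0.5, 0.9, 0.9)), 0.75)
  y <- sort(rnorm(20))
  expect_equal(concordance_index(y, 2 * y + 5), 1)
  expect_error(concordance_index(c(1, 1), c(0.2, 0.4)),
               class = "psinter_metric_undefined")
})

test_that("concordance index is invariant under monotone transforms", {
  set.seed(7)
  y <- rnorm(60); p <- y + rnorm(60)
  ci <- concordance_index(y, p)
  expect_equal(concordance_index(y, exp(p)), ci)
  expect_equal(concordance_index(y, rank(p)), ci)
})

test_that("rm-squared collapses and clips as specified", {
  y <- c(1, 2, 3, 4.2)
  out <- rm_squared(y, y)
  expect_equal(out$rm_squared, 1)
  expect_equal(out$r2, out$r02)
  # an exact through-origin relation: the with-intercept fit has
  # intercept 0, so r02 = r2 and rm2 = r2
  set.seed(3)
  yhat <- rnorm(30)
  out2 <- rm_squared(2 * yhat, yhat)
  expect_equal(out2$r02, out2$r2, tolerance = 1e-12)
  expect_equal(out2$rm_squared, out2$r2, tolerance = 1e-12)
})

test_that("binary metrics match confusion-table arithmetic", {
  expect_equal(mcc_from_confusion(3, 5, 1, 1), 14 / 24)
  # build vectors realizing TP=3 TN=5 FP=1 FN=1
  y <- c(rep(1, 3), rep(0, 5), 0, 1)
  p <- c(rep(0.9, 3), rep(0.1, 5), 0.8, 0.2)
  m <- binary_metrics(y, p)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$mcc, 14 / 24)

  sep <- binary_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(unlist(sep), c(accuracy = 1, mcc = 1, roc_auc = 1))

  expect_error(binary_metrics(c(1, 1, 1), c(0.2, 0.6, 0.9)),
               class = "psinter_metric_undefined")
  expect_error(mcc_from_confusion(0, 5, 0, 5),
               class = "psinter_metric_undefined")
})

test_that("MCC is symmetric under class swap", {
  set.seed(11)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.4)
    p <- runif(30)
    if (length(unique(y)) < 2) next
    m1 <- binary_metrics(y, p)$mcc
    m2 <- binary_metrics(1 - y, 1 - p)$mcc
    expect_equal(m1, m2, tolerance = 1e-12)
  }
})

test_that("roc_auc equals the concordance index on binary labels", {
  set.seed(13)
  for (i in 1:15) {
    y <- rbinom(25, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(25), 1)  # force some ties
    expect_equal(binary_metrics(y, p)$roc_auc, concordance_index(y, p))
    expect_equal(binary_metrics(y, p)$roc_auc, oracle_auc(y, p))
  }
})

test_that("metrics agree with an external reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  y <- rbinom(80, 1, 0.35); p <- runif(80)
  auc_ref <- as.numeric(suppressMessages(pROC::auc(y, p)))
  expect_equal(binary_metrics(y, p)$roc_auc, auc_ref, tolerance = 1e-12)
})
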