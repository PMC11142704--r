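#' Regression metrics: MSE, coefficient of determination, Pearson r
#'
#' `r_squared` is the coefficient of determination `1 - SSres/SStot`
#' (which can be negative and differs from the squared Pearson
#' correlation for a miscalibrated model).
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return named list with `mse`, `r_squared`, `pearson_r`.
#' @export
regression_metrics <- function(y, yhat) {
  check_paired(y, yhat, min_n = 2L)
  mse <- mean((y - yhat)^2)
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0)
    ps_abort("r_squared is undefined: observed values have zero variance",
             "psinter_metric_undefined")
  r_squared <- 1 - sum((y - yhat)^2) / sstot
  if (stats::var(yhat) == 0)
    ps_abort("pearson_r is undefined: predictions have zero variance",
             "psinter_metric_undefined")
  list(mse = mse, r_squared = r_squared,
       pearson_r = stats::cor(y, yhat))
}

#' Concordance index
#'
#' The fraction of correctly ordered pairs among all comparable pairs
#' (pairs with different observed values). Pairs whose predictions are
#' tied contribute 1/2; pairs with tied observed values are excluded.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return concordance index in `[0, 1]`.
#' @examples
#' concordance_index(c(1, 2, 3), c(0.1, 0.3, 0.2))  # 2/3
#' @export
concordance_index <- function(y, yhat) {
  check_paired(y, yhat, min_n = 2L)
  dy <- sign(outer(y, y, "-"))
  dp <- sign(outer(yhat, yhat, "-"))
  upper <- upper.tri(dy)
  comparable <- upper & dy != 0
  n_comp <- sum(comparable)
  if (n_comp == 0)
    ps_abort("concordance index is undefined: no comparable pairs",
             "psinter_metric_undefined")
  concordant <- sum(dy[comparable] == dp[comparable])
  pred_ties <- sum(dp[comparable] == 0)
  (concordant + 0.5 * pred_ties) / n_comp
}

#' The rm-squared QSAR validation metric
#'
#' `rm2 = r2 * (1 - sqrt(r2 - r02))`, where `r2` is the squared Pearson
#' correlation between observed and predicted values (least squares with
#' intercept) and `r02` is the coefficient of determination of the
#' through-origin fit of observed on predicted
#' (`r02 = 1 - sum((y - k*yhat)^2) / sum((y - mean(y))^2)` with
#' `k = sum(y*yhat) / sum(yhat^2)`). The metric penalizes divergence
#' between the with-intercept and through-origin fits, i.e. systematic
#' offset or scale bias in otherwise well-correlated predictions.
#'
#' A negative radicand `r2 - r02` (possible in degenerate cases through
#' rounding) is clipped to zero with a warning. `radical = FALSE` gives
#' the non-radical variant `r2 * (1 - (r2 - r02))`.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @param radical use the square-root form (default).
#' @return named list with `rm_squared`, `r2`, `r02`.
#' @export
rm_squared <- function(y, yhat, radical = TRUE) {
  check_paired(y, yhat, min_n = 3L)
  if (stats::var(y) == 0 || stats::var(yhat) == 0)
    ps_abort("rm_squared is undefined for zero-variance inputs",
             "psinter_metric_undefined")
  if (sum(yhat^2) == 0)
    ps_abort("through-origin fit undefined: predictions are all zero",
             "psinter_metric_undefined")
  r2 <- stats::cor(y, yhat)^2
  k <- sum(y * yhat) / sum(yhat^2)
  r02 <- 1 - sum((y - k * yhat)^2) / sum((y - mean(y))^2)
  rad <- r2 - r02
  if (rad < 0) {
    if (rad < -1e-8)
      ps_warn(sprintf("negative radicand r2 - r02 = %.3g clipped to 0", rad),
              "psinter_rm2_clip")
    rad <- 0
  }
  rm2 <- if (radical) r2 * (1 - sqrt(rad)) else r2 * (1 - rad)
  list(rm_squared = rm2, r2 = r2, r02 = r02)
}

#' Binary classification metrics: accuracy, MCC, ROC-AUC
#'
#' MCC is the Matthews correlation coefficient from the 2x2 confusion
#' table at `threshold`. ROC-AUC is the probability that a randomly drawn
#' positive outranks a randomly drawn negative, with ties credited 1/2
#' (computed by the rank/Wilcoxon identity).
#'
#' @param y 0/1 labels.
#' @param p predicted probabilities or scores.
#' @param threshold classification threshold for accuracy and MCC.
#' @return named list with `accuracy`, `mcc`, `roc_auc` (the latter two
#'   are only defined when both classes are present).
#' @export
binary_metrics <- function(y, p, threshold = 0.5) {
  check_paired(y, p, min_n = 1L)
  if (!all(y %in% c(0, 1)))
    ps_abort("`y` must contain only 0/1 labels", "psinter_value_error")
  yhat <- as.numeric(p >= threshold)
  accuracy <- mean(yhat == y)
  if (length(unique(y)) < 2L)
    ps_abort("mcc and roc_auc are undefined for single-class labels (accuracy only)",
             "psinter_metric_undefined", accuracy = accuracy)
  tp <- sum(y == 1 & yhat == 1); tn <- sum(y == 0 & yhat == 0)
  fp <- sum(y == 0 & yhat == 1); fn <- sum(y == 1 & yhat == 0)
  mcc <- mcc_from_confusion(tp, tn, fp, fn)
  r <- rank(p)  # average ranks give ties the 1/2 credit
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  roc_auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(accuracy = accuracy, mcc = mcc, roc_auc = roc_auc)
}

#' Matthews correlation coefficient from a confusion table
#'
#' @param tp,tn,fp,fn confusion-table counts.
#' @return MCC in `[-1, 1]`; errors when a marginal is zero.
#' @examples
#' mcc_from_confusion(3, 5, 1, 1)  # 14/24
#' @export
mcc_from_confusion <- function(tp, tn, fp, fn) {
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0)
    ps_abort("MCC undefined: a confusion-table marginal is zero",
             "psinter_metric_undefined")
  (tp * tn - fp * fn) / denom
}

#' Compute a full metric report for one task
#'
#' Convenience wrapper producing all task-appropriate metrics in one list.
#'
#' @param y observed values (0/1 for classification).
#' @param yhat predictions (probabilities for classification).
#' @param task `"regression"` or `"binary_classification"`.
#' @return named list of metric values (a `metric_report`).
#' @export
metric_report <- function(y, yhat, task = c("regression", "binary_classification")) {
  task <- match.arg(task)
  if (task == "regression") {
    out <- regression_metrics(y, yhat)
    out$concordance_index <- concordance_index(y, yhat)
    rm2 <- rm_squared(y, yhat)
    out$rm_squared <- rm2$rm_squared
    out$rm2_r2 <- rm2$r2
    out$rm2_r02 <- rm2$r02
  } else {
    out <- binary_metrics(y, yhat)
  }
  structure(out, class = "metric_report", task = task, n = length(y))
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> task: %s  n = %d\n", attr(x, "task"), attr(x, "n")))
  for (nm in names(x)) cat(sprintf("  %-17s %.4f\n", nm, x[[nm]]))
  invisible(x)
}

check_paired <- function(y, yhat, min_n) {
  if (length(y) != length(yhat))
    ps_abort("observed and predicted vectors must have equal length",
             "psinter_shape_error")
  if (length(y) < min_n)
    ps_abort(sprintf("need at least %d observations", min_n),
             "psinter_value_error")
  if (anyNA(y) || anyNA(yhat) || !all(is.finite(y)) || !all(is.finite(yhat)))
    ps_abort("metric inputs must be finite and non-missing",
             "psinter_value_error")
  invisible(TRUE)
}
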