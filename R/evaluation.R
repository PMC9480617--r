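#' Root mean squared error
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length).
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (!length(y)) stop("empty input", call. = FALSE)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  sqrt(mean((y - yhat)^2))
}

# Pearson correlation with the baseline convention: a constant prediction
# vector has no defined correlation and is reported as 0 (degenerate).
pearson_or_zero <- function(y, yhat) {
  if (sd(yhat) == 0 || sd(y) == 0)
    return(structure(0, degenerate = TRUE))
  structure(cor(y, yhat), degenerate = FALSE)
}

#' Accuracy, sensitivity and specificity of a probabilistic classifier
#'
#' The positive class (label 1, "mindful" in the trait-mindfulness
#' application) is predicted when the probability reaches `threshold`.
#' Sensitivity is the fraction of positive examples correctly classified,
#' specificity the fraction of negative examples correctly classified.
#'
#' @param y Binary 0/1 labels (both classes present).
#' @param yhat_prob Predicted probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return List with `accuracy`, `sensitivity`, `specificity` and the
#'   confusion counts `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_metrics <- function(y, yhat_prob, threshold = 0.5) {
  if (length(y) != length(yhat_prob)) stop("length mismatch", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (all(y == 1)) stop("specificity undefined: no negative examples",
                        call. = FALSE)
  if (all(y == 0)) stop("sensitivity undefined: no positive examples",
                        call. = FALSE)
  pred <- as.integer(yhat_prob >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  list(accuracy = (tp + tn) / length(y),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       tp = tp, fn = fn, tn = tn, fp = fp)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the unique scores to trace the ROC
#' curve (false positive rate vs true positive rate); the AUC is computed by
#' the rank statistic (tie-averaged), i.e. the probability that a randomly
#' chosen positive example scores higher than a randomly chosen negative
#' one, which equals the trapezoidal area under the tie-averaged curve.
#'
#' @param y Binary 0/1 labels (both classes present).
#' @param scores Classifier scores (any strictly increasing transform of the
#'   probability gives the same AUC).
#' @return List with `roc_points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(y, scores) {
  if (length(y) != length(scores)) stop("length mismatch", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present",
                                   call. = FALSE)
  pos <- sum(y == 1); neg <- sum(y == 0)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) sum(scores >= t & y == 1) / pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores >= t & y == 0) / neg,
                numeric(1))
  roc_points <- data.frame(threshold = c(Inf, thresholds),
                           fpr = c(0, fpr), tpr = c(0, tpr))
  r <- rank(scores)  # ties get average ranks -> concordance AUC
  auc <- (sum(r[y == 1]) - pos * (pos + 1) / 2) / (pos * neg)
  list(roc_points = roc_points, auc = auc)
}

#' Baseline models
#'
#' `baseline_regression` predicts every test example as the mean response of
#' the training/validation set; its correlation with the observations is
#' reported as 0 by convention (constant predictions have undefined
#' correlation). `baseline_classifier` assigns each example to one of the
#' two classes with equal probability (seeded), the natural reference for
#' balanced classes with 50% expected accuracy.
#'
#' @param y_trainval Training/validation responses.
#' @param n_test Number of test examples.
#' @return `baseline_regression`: numeric predictions. `baseline_classifier`:
#'   integer 0/1 labels.
#' @export
baseline_regression <- function(y_trainval, n_test) {
  if (!length(y_trainval)) stop("empty training/validation set",
                                call. = FALSE)
  if (n_test < 1L) stop("n_test must be >= 1", call. = FALSE)
  rep(mean(y_trainval), n_test)
}

#' @rdname baseline_regression
#' @param seed Seed of the random label draw.
#' @export
baseline_classifier <- function(n_test, seed = 1L) {
  if (n_test < 1L) stop("n_test must be >= 1", call. = FALSE)
  with_seed(seed, sample(c(0L, 1L), n_test, replace = TRUE))
}

#' Evaluate a regression model against the mean-predictor baseline
#'
#' @param model A fitted `slnn` (regression).
#' @param x_test,y_test Held-out inputs and responses.
#' @param y_trainval Training/validation responses (for the baseline mean).
#' @return List of class `evaluation_report` with `rmse`, `pearson_r`,
#'   `baseline` (`rmse`, `pearson_r = 0`) and the predictions.
#' @export
evaluate_regression <- function(model, x_test, y_test, y_trainval) {
  yhat <- predict(model, x_test)
  base <- baseline_regression(y_trainval, length(y_test))
  structure(list(task = "regression",
                 rmse = rmse(y_test, yhat),
                 pearson_r = as.numeric(pearson_or_zero(y_test, yhat)),
                 baseline = list(rmse = rmse(y_test, base),
                                 pearson_r = as.numeric(pearson_or_zero(y_test, base))),
                 predictions = yhat),
            class = "evaluation_report")
}

#' Evaluate a classifier against the random-classifier baseline
#'
#' @param model A fitted `slnn` (classification).
#' @param x_test Held-out inputs.
#' @param y_test Held-out 0/1 labels.
#' @param baseline_seed Seed of the random baseline labels.
#' @return List of class `evaluation_report` with `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `roc_points`, and the baseline metrics.
#' @export
evaluate_classifier <- function(model, x_test, y_test, baseline_seed = 1L) {
  prob <- predict(model, x_test)
  cm <- confusion_metrics(y_test, prob)
  roc <- roc_auc(y_test, prob)
  base_labels <- baseline_classifier(length(y_test), baseline_seed)
  base_acc <- mean(base_labels == y_test)
  structure(list(task = "classification",
                 accuracy = cm$accuracy, sensitivity = cm$sensitivity,
                 specificity = cm$specificity, auc = roc$auc,
                 roc_points = roc$roc_points,
                 baseline = list(accuracy = base_acc, auc = 0.5),
                 predictions = prob),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  if (x$task == "regression") {
    cat(sprintf("Regression evaluation: RMSE %.3f (baseline %.3f), Pearson r %.3f\n",
                x$rmse, x$baseline$rmse, x$pearson_r))
  } else {
    cat(sprintf("Classification evaluation: accuracy %.1f%% (baseline %.1f%%), AUC %.3f, sensitivity %.2f, specificity %.2f\n",
                100 * x$accuracy, 100 * x$baseline$accuracy, x$auc,
                x$sensitivity, x$specificity))
  }
  invisible(x)
}
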