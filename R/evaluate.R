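#' Classification performance evaluation
#'
#' Malignant is the positive class throughout: sensitivity is the
#' true-positive rate among malignant cases, specificity the true-negative
#' rate among benign cases. Metrics are reported as percentages.
#'
#' @name evaluate
NULL

#' Confusion counts from predictions and truth
#'
#' @param predicted,truth benign/malignant labels of equal length.
#' @return Named list `TP`, `FN`, `TN`, `FP` (malignant = positive).
#' @export
confusion_counts <- function(predicted, truth) {
  p <- as_label_factor(predicted)
  t_ <- as_label_factor(truth)
  if (length(p) != length(t_)) abort("length mismatch", class = "busfusion_contract_error")
  list(
    TP = sum(p == "malignant" & t_ == "malignant"),
    FN = sum(p == "benign" & t_ == "malignant"),
    TN = sum(p == "benign" & t_ == "benign"),
    FP = sum(p == "malignant" & t_ == "benign")
  )
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (TP + TN) / n`, `sensitivity = TP / (TP + FN)`,
#' `specificity = TN / (TN + FP)`, each expressed as a percentage. The
#' weighted identity
#' `accuracy = (sensitivity * n_pos + specificity * n_neg) / n` holds
#' exactly.
#'
#' @param TP,FN,TN,FP Non-negative confusion counts, or a single list with
#'   those names as the first argument.
#' @return Tibble with columns `accuracy`, `sensitivity`, `specificity`
#'   (percent).
#' @export
#' @examples
#' confusion_metrics(TP = 50, FN = 3, TN = 32, FP = 5)
confusion_metrics <- function(TP, FN = NULL, TN = NULL, FP = NULL) {
  if (is.list(TP)) {
    cc <- TP
    TP <- cc$TP; FN <- cc$FN; TN <- cc$TN; FP <- cc$FP
  }
  counts <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("confusion counts must be non-negative integers", class = "busfusion_contract_error")
  }
  if (TP + FN == 0 || TN + FP == 0) {
    abort("both classes must be present to define sensitivity and specificity",
      class = "busfusion_metric_error"
    )
  }
  n <- TP + FN + TN + FP
  tibble::tibble(
    accuracy = 100 * (TP + TN) / n,
    sensitivity = 100 * TP / (TP + FN),
    specificity = 100 * TN / (TN + FP)
  )
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (plus infinite
#' endpoints, so the curve runs exactly from (0, 0) to (1, 1)), predicting
#' malignant where `score >= threshold`. AUC is the trapezoid-rule area,
#' which equals the normalized Mann-Whitney pairwise-concordance statistic
#' (ties counted half).
#'
#' @param scores Numeric malignancy scores.
#' @param labels benign/malignant truth.
#' @return Object of class `roc_curve`: tibble with columns `threshold`,
#'   `fpr`, `tpr`, and attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_label_factor(labels)
  if (length(scores) != length(y)) abort("length mismatch", class = "busfusion_contract_error")
  n_pos <- sum(y == "malignant"); n_neg <- sum(y == "benign")
  if (n_pos == 0 || n_neg == 0) abort("both classes required for ROC", class = "busfusion_metric_error")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t_) sum(scores >= t_ & y == "malignant") / n_pos, numeric(1))
  fpr <- vapply(thr, function(t_) sum(scores >= t_ & y == "benign") / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(
    tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr),
    auc = auc, class = c("roc_curve", class(tibble::tibble()))
  )
}

#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), n_thresholds = nrow(x))
}

#' Area under an ROC curve
#'
#' @param x A [roc_curve()] object.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(x) {
  if (!inherits(x, "roc_curve")) abort("`x` must be a roc_curve", class = "busfusion_type_error")
  attr(x, "auc")
}

#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate (1 - specificity)",
      y = "True-positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.4f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Metrics across a grid of fusion weights
#'
#' Re-fuses the fixed test-set channel scores at every `lambda` in the
#' grid and evaluates accuracy, sensitivity, specificity and AUC. The
#' endpoints `lambda = 0` and `lambda = 1` reproduce the single-channel
#' results exactly.
#'
#' @param s_svm,s_nb Channel scores on the test set.
#' @param labels benign/malignant truth.
#' @param grid Lambda grid (default `seq(0, 1, 0.1)`).
#' @return Tibble with one row per lambda, class `lambda_sweep`.
#' @export
lambda_sweep <- function(s_svm, s_nb, labels, grid = seq(0, 1, by = 0.1)) {
  y <- as_label_factor(labels)
  rows <- purrr::map(grid, function(lam) {
    fused <- fuse_scores(s_svm, s_nb, lambda = lam)
    met <- confusion_metrics(confusion_counts(fused$label, y))
    dplyr::bind_cols(tibble::tibble(lambda = lam), met,
      tibble::tibble(auc = attr(roc_curve(fused$s_c, y), "auc"))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lambda_sweep", class(out))
  out
}

#' @method autoplot lambda_sweep
#' @export
autoplot.lambda_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object)[, c("lambda", "accuracy", "sensitivity", "specificity")],
    -"lambda", names_to = "metric", values_to = "percent"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lambda, y = .data$percent, color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = expression(lambda), y = "Percent", color = NULL,
      title = "Fusion-weight sweep") +
    ggplot2::theme_minimal()
}
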