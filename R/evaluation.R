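#' Corrected resampled t confidence interval for repeated-split accuracies
#'
#' Accuracies from repeated random splits of one dataset are dependent, so
#' the naive t interval is anti-conservative. The corrected interval
#' inflates the variance by `1/n_splits + n_te/n_tr`:
#' `mean(v) +/- sd(v) * sqrt(1/n + n_te/n_tr) * t_{n-1, (1+level)/2}`.
#'
#' @param values Per-split accuracies (at least two), fraction or percent
#'   scale (the formula is scale-equivariant).
#' @param n_tr Number of training subjects per split.
#' @param n_te Number of tested subjects per split.
#' @param level Confidence level (default 0.95).
#' @return List with `mean`, `sd`, `lower`, `upper`, `half_width`.
#' @export
corrected_resampled_ci <- function(values, n_tr, n_te, level = 0.95) {
  n <- length(values)
  if (n < 2) stopf("need at least two splits (sd undefined for one)")
  if (n_tr < 1 || n_te < 1) stopf("n_tr and n_te must be >= 1")
  m <- mean(values)
  s <- stats::sd(values)
  tq <- stats::qt((1 + level) / 2, df = n - 1)
  hw <- s * sqrt(1 / n + n_te / n_tr) * tq
  list(mean = m, sd = s, lower = m - hw, upper = m + hw, half_width = hw)
}

#' Confusion matrix of a leave-one-out result
#'
#' Rows are the true class, columns the predicted class.
#'
#' @param result A `loo_result` or data frame with `true` and `predicted`
#'   columns.
#' @param classes Optional class order; defaults to the union of observed
#'   labels.
#' @return Integer matrix of counts.
#' @export
confusion_matrix <- function(result, classes = NULL) {
  df <- if (inherits(result, "loo_result")) result$predictions else as.data.frame(result)
  if (nrow(df) == 0) stopf("empty result")
  if (is.null(classes)) classes <- sort(unique(c(df$true, df$predicted)))
  tab <- table(factor(df$true, levels = classes),
               factor(df$predicted, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Sensitivity and specificity for a binary result
#'
#' `sens = TP / (TP + FN)`, `spec = TN / (TN + FP)` with respect to the
#' given positive class.
#'
#' @param result A `loo_result` or data frame with `true`/`predicted`.
#' @param positive_class The positive label (e.g. `"Het"`).
#' @return List with `sensitivity` and `specificity`.
#' @export
sensitivity_specificity <- function(result, positive_class) {
  df <- if (inherits(result, "loo_result")) result$predictions else as.data.frame(result)
  pos <- df$true == positive_class
  tp <- sum(pos & df$predicted == positive_class)
  fn <- sum(pos & df$predicted != positive_class)
  tn <- sum(!pos & df$predicted != positive_class)
  fp <- sum(!pos & df$predicted == positive_class)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# Rank-based AUC (equals the Mann-Whitney U statistic normalized by
# n_pos * n_neg; tied scores count 1/2 via midranks).
auc_rank <- function(scores, labels) {
  pos <- labels == 1
  r <- rank(scores)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

# ROC points from a threshold sweep over unique scores (descending).
roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o] == 1
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # collapse tied scores
  data.frame(fpr = c(0, fp[keep] / max(sum(!y), 1)),
             tpr = c(0, tp[keep] / max(sum(y), 1)))
}

#' Per-split and merged ROC curves with AUC
#'
#' Computes a threshold-sweep ROC and rank-based AUC for each split, then a
#' merged ROC/AUC from the pooled score-label pairs across splits. Splits
#' with a single class are skipped with a warning. Tied scores contribute
#' 1/2 (Mann-Whitney convention).
#'
#' @param per_split List of lists, each with `scores` (positive-class
#'   probabilities) and `labels` (1 = positive, 0 = negative).
#' @return List with `roc` (per-split ROC point data frames), `auc`
#'   (per-split AUCs), `merged_roc`, `merged_auc`.
#' @export
merge_roc <- function(per_split) {
  aucs <- numeric(0)
  rocs <- list()
  all_s <- all_y <- numeric(0)
  for (i in seq_along(per_split)) {
    s <- per_split[[i]]$scores
    y <- as.numeric(per_split[[i]]$labels)
    if (length(unique(y)) < 2) {
      warning(sprintf("split %d has a single class; skipped", i))
      aucs <- c(aucs, NA_real_)
      rocs[[i]] <- NULL
      next
    }
    aucs <- c(aucs, auc_rank(s, y))
    rocs[[i]] <- roc_points(s, y)
    all_s <- c(all_s, s); all_y <- c(all_y, y)
  }
  list(roc = rocs, auc = aucs,
       merged_roc = if (length(unique(all_y)) == 2) roc_points(all_s, all_y) else NULL,
       merged_auc = if (length(unique(all_y)) == 2) auc_rank(all_s, all_y) else NA_real_)
}
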