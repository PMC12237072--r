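#' Classification and calibration metrics
#'
#' Computes the evaluation suite used throughout the workflow from
#' predicted probabilities, binary truths and a decision threshold:
#' Cohen's kappa = (p_o - p_e) / (1 - p_e); the Matthews correlation
#' coefficient from the confusion matrix; mean squared error of the
#' probabilities; sensitivity TP/(TP+FN); specificity TN/(TN+FP); and the
#' area under the precision-recall curve by step-wise integration over all
#' distinct thresholds. A single-class truth vector leaves kappa and MCC
#' undefined (NA, with a warning).
#'
#' @param prob predicted probabilities in [0, 1].
#' @param truth binary outcomes (0/1).
#' @param threshold decision threshold for the binary metrics (default 0.5).
#' @return list with `kappa`, `mcc`, `mse`, `sensitivity`, `specificity`,
#'   `pr_auc`, `threshold`.
#' @export
compute_metrics <- function(prob, truth, threshold = 0.5) {
  stopifnot(length(prob) == length(truth))
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  n <- length(truth)
  single_class <- length(unique(truth)) < 2
  if (single_class)
    warning("single-class truth vector: kappa and MCC undefined")
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (single_class || p_e == 1) NA_real_ else (p_o - p_e) / (1 - p_e)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (single_class || mcc_den == 0) NA_real_ else
    (tp * tn - fp * fn) / mcc_den
  list(kappa = kappa, mcc = mcc,
       mse = mean((prob - truth)^2),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       pr_auc = pr_auc(prob, truth),
       threshold = threshold)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration: thresholds at every distinct predicted value in
#' descending order; the curve steps in recall and the area accumulates
#' precision * delta-recall (the "step" estimator, exact for finite
#' samples).
#'
#' @param prob predicted probabilities.
#' @param truth binary outcomes.
#' @return scalar PR-AUC in [0, 1]; NA when no positives exist.
#' @export
pr_auc <- function(prob, truth) {
  n_pos <- sum(truth == 1)
  if (n_pos == 0) return(NA_real_)
  ord <- order(prob, decreasing = TRUE)
  t_sorted <- truth[ord]
  p_sorted <- prob[ord]
  tp <- cumsum(t_sorted == 1)
  fp <- cumsum(t_sorted == 0)
  # evaluate only at the last index of each tied probability block
  last_of_block <- c(p_sorted[-1] != p_sorted[-length(p_sorted)], TRUE)
  tp <- tp[last_of_block]; fp <- fp[last_of_block]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  d_rec <- diff(c(0, recall))
  sum(precision * d_rec)
}

#' Threshold maximizing MCC on a prediction set
#'
#' @param prob predicted probabilities (typically training predictions).
#' @param truth binary outcomes.
#' @return the probability value (midpoint between adjacent distinct
#'   predictions) with maximal MCC; 0.5 for degenerate inputs.
#' @export
best_mcc_threshold <- function(prob, truth) {
  if (length(unique(truth)) < 2) return(0.5)
  cand <- sort(unique(prob))
  if (length(cand) > 200) cand <- stats::quantile(prob, seq(0.005, 0.995, length.out = 200))
  cand <- unique(c(cand, 0.5))
  mccs <- vapply(cand, function(th) {
    m <- suppressWarnings(compute_metrics(prob, truth, th))
    if (is.na(m$mcc)) -Inf else m$mcc
  }, 0)
  cand[which.max(mccs)]
}
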