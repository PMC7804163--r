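#' Classification performance metrics
#'
#' Sensitivity, specificity and accuracy in percent (tumor = positive class
#' +1), and AUC as the probability that a random positive sample receives a
#' higher decision score than a random negative one, with ties counted 1/2
#' (equivalent to the trapezoidal area under the ROC curve). Computed by the
#' rank formulation of the Mann-Whitney statistic.
#'
#' @param labels true labels in \{-1, +1\}
#' @param predicted predicted labels in \{-1, +1\}
#' @param scores continuous decision values (same length); required for AUC
#' @return list with `sensitivity`, `specificity`, `accuracy` (percent) and
#'   `auc`; metrics needing an absent class are `NA` with a warning
#' @export
compute_metrics <- function(labels, predicted, scores = NULL) {
  stopifnot(length(labels) == length(predicted),
            all(labels %in% c(-1, 1)), all(predicted %in% c(-1, 1)))
  tp <- sum(labels == 1 & predicted == 1)
  fn <- sum(labels == 1 & predicted == -1)
  tn <- sum(labels == -1 & predicted == -1)
  fp <- sum(labels == -1 & predicted == 1)
  n_pos <- tp + fn
  n_neg <- tn + fp
  if (n_pos == 0 || n_neg == 0)
    warning("a class is absent; sensitivity/specificity/AUC undefined")
  sens <- if (n_pos > 0) 100 * tp / n_pos else NA_real_
  spec <- if (n_neg > 0) 100 * tn / n_neg else NA_real_
  acc <- 100 * (tp + tn) / length(labels)
  auc <- NA_real_
  if (!is.null(scores) && n_pos > 0 && n_neg > 0) {
    r <- rank(scores)  # average ranks handle ties as 1/2
    auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  list(sensitivity = sens, specificity = spec, accuracy = acc, auc = auc)
}
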