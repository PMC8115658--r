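#' Area under the ROC curve from association scores
#'
#' Rank-based (Mann-Whitney) AUC of `-log10(p)` scores against binary
#' causal labels, with midrank handling of ties. 1.0 means all top
#' signals are true causal markers; 0.5 means no power.
#'
#' @param scores Numeric scores (larger = more significant); markers with
#'   `NA` scores are dropped with a warning.
#' @param truth Logical or 0/1 causal labels, aligned with `scores`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  keep <- !is.na(scores) & !is.na(truth)
  if (any(!keep)) {
    warning(sum(!keep), " marker(s) with NA score dropped")
    scores <- scores[keep]; truth <- truth[keep]
  }
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("both causal and non-causal markers are required")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity (true positive rate) at a fixed false positive rate
#'
#' Evaluates the ROC step function at the score threshold whose empirical
#' false positive rate is the largest value not exceeding `fpr`.
#'
#' @inheritParams roc_auc
#' @param fpr Target false positive rate (default 0.05).
#' @return True positive rate in `[0, 1]`.
#' @export
sensitivity_at_fpr <- function(scores, truth, fpr = 0.05) {
  truth <- as.logical(truth)
  keep <- !is.na(scores) & !is.na(truth)
  scores <- scores[keep]; truth <- truth[keep]
  if (sum(truth) == 0L || sum(!truth) == 0L)
    stop("both causal and non-causal markers are required")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  fprs <- vapply(thr, function(t) mean(scores[!truth] >= t), numeric(1))
  tprs <- vapply(thr, function(t) mean(scores[truth] >= t), numeric(1))
  ok <- which(fprs <= fpr)
  max(tprs[ok])
}

#' Mean absolute error of effect-size estimates
#'
#' The simulator standardizes phenotypes, so true coefficients are
#' compared against estimates multiplied by the standard deviation of the
#' non-standardized phenotype.
#'
#' @param beta_true True coefficients of the causal markers.
#' @param beta_hat Estimated coefficients, aligned with `beta_true`.
#' @param sd_raw_y Standard deviation of the raw (non-standardized)
#'   phenotype (`sd_raw` from [simulate_phenotype()]).
#' @return Mean of `|beta_true - beta_hat * sd_raw_y|` over complete
#'   pairs; `NA` if the class is empty.
#' @export
mae_effects <- function(beta_true, beta_hat, sd_raw_y) {
  stopifnot(length(beta_true) == length(beta_hat))
  if (length(beta_true) == 0L) return(NA_real_)
  d <- abs(beta_true - beta_hat * sd_raw_y)
  mean(d, na.rm = TRUE)
}

#' Signed relative error of the total PVE estimate
#'
#' `(estimated - true) / true`: 0 is exact, positive overestimates.
#'
#' @param est_total Estimated total PVE.
#' @param true_total True total PVE (> 0).
#' @return Signed relative error.
#' @export
pve_accuracy <- function(est_total, true_total) {
  if (true_total <= 0) stop("true_total must be > 0")
  (est_total - true_total) / true_total
}
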