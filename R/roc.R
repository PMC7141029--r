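#' ROC analysis with DeLong confidence interval
#'
#' AUC is computed through the Mann-Whitney identity (tied pairs count
#' one half) and its 95% confidence interval with the DeLong placement
#' variance estimator. The operating threshold maximizes balanced accuracy
#' `(sensitivity + specificity) / 2` over midpoint candidates on the
#' supplied probabilities (smallest maximizer on ties; a sample is called
#' positive iff its probability is strictly greater than the threshold),
#' and accuracy, sensitivity and specificity are reported at it.
#'
#' @param probabilities per-sample scores or probabilities.
#' @param labels case/control labels (both classes required).
#' @return object of class `roc_result`: auc, auc_ci_low, auc_ci_high,
#'   accuracy, sensitivity, specificity, threshold, and the per-sample
#'   `probabilities` tibble.
#' @export
roc_analysis <- function(probabilities, labels) {
  y <- .case_indicator(labels)
  if (length(probabilities) != length(y)) {
    abort("probabilities and labels differ in length")
  }
  p1 <- probabilities[y]
  p0 <- probabilities[!y]
  n1 <- length(p1)
  n0 <- length(p0)

  # placements: V10_i = P(case_i beats a control), V01_j likewise
  psi <- outer(p1, p0, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- 1 - colMeans(psi)  # orientation: P(control loses)
  auc <- mean(psi)
  var_auc <- (if (n1 > 1) stats::var(v10) / n1 else 0) +
    (if (n0 > 1) stats::var(1 - v01) / n0 else 0)
  se <- sqrt(max(var_auc, 0))
  ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))

  cand <- .candidate_cutpoints(probabilities)
  ba <- vapply(cand, function(cc) {
    (mean(p1 > cc) + mean(p0 <= cc)) / 2
  }, 0)
  thr <- cand[which(ba >= max(ba) - 1e-12)[1]]
  sens <- mean(p1 > thr)
  spec <- mean(p0 <= thr)
  acc <- (sum(p1 > thr) + sum(p0 <= thr)) / (n1 + n0)

  structure(list(auc = auc, auc_ci_low = ci[1], auc_ci_high = ci[2],
                 accuracy = acc, sensitivity = sens, specificity = spec,
                 threshold = thr,
                 probabilities = tibble(
                   sample = seq_along(probabilities),
                   label = ifelse(y, "case", "control"),
                   probability = as.numeric(probabilities))),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f); acc %.3f, sens %.3f, spec %.3f @ thr %.4g\n",
              x$auc, x$auc_ci_low, x$auc_ci_high, x$accuracy,
              x$sensitivity, x$specificity, x$threshold))
  invisible(x)
}

#' DeLong paired test for two correlated AUCs
#'
#' Two-sided test that two classifiers evaluated on the same samples have
#' equal AUC, using the DeLong covariance of the paired placement values.
#' Identical score vectors give p = 1.
#'
#' @param roc_a,roc_b [roc_analysis()] results computed on the same
#'   samples (same length and labels, in the same order).
#' @return two-sided p-value.
#' @export
compare_auc <- function(roc_a, roc_b) {
  la <- roc_a$probabilities$label
  lb <- roc_b$probabilities$label
  if (length(la) != length(lb) || !all(la == lb)) {
    abort("ROC results were not computed on the same samples")
  }
  y <- la == "case"
  place <- function(p) {
    psi <- outer(p[y], p[!y], function(a, b) (a > b) + 0.5 * (a == b))
    list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
  }
  a <- place(roc_a$probabilities$probability)
  b <- place(roc_b$probabilities$probability)
  n1 <- sum(y)
  n0 <- sum(!y)
  s <- (if (n1 > 1) stats::var(a$v10 - b$v10) / n1 else 0) +
    (if (n0 > 1) stats::var(a$v01 - b$v01) / n0 else 0)
  d <- a$auc - b$auc
  if (s <= 0) return(if (abs(d) < 1e-12) 1 else 0)
  2 * stats::pnorm(-abs(d) / sqrt(s))
}
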