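#' Area under the ROC curve for presence/background scores
#'
#' The probability that a randomly chosen presence is scored above a
#' randomly chosen background point, ties counted one half — computed from
#' the normalized Wilcoxon rank sum, which equals the exhaustive pairwise
#' average exactly.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector (1 = presence).
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stopf("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' True skill statistic at a threshold, and its maximum over thresholds
#'
#' TSS = sensitivity + specificity - 1, where a point is predicted present
#' when its score is >= the threshold. \code{maxTss} scans every midpoint
#' between adjacent unique scores plus one candidate below the minimum and
#' one above the maximum, and returns the maximizing TSS with the smallest
#' maximizing threshold on ties.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector (1 = presence).
#' @param threshold decision threshold.
#' @return \code{tssAt}: the TSS. \code{maxTss}: list(tss, threshold,
#'   sensitivity, specificity).
#' @export
tssAt <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stopf("both classes must be present to compute TSS")
  pred <- scores >= threshold
  sens <- sum(pred & labels == 1) / np
  spec <- sum(!pred & labels == 0) / nn
  sens + spec - 1
}

#' @rdname tssAt
#' @export
maxTss <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- if (length(u) == 1) c(u - 1, u + 1)
  else c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  vals <- vapply(cand, function(th) tssAt(scores, labels, th), numeric(1))
  best <- which(vals >= max(vals) - 1e-12)[1]  # smallest threshold on ties
  th <- cand[best]
  labels <- as.integer(labels)
  pred <- scores >= th
  list(tss = vals[best], threshold = th,
       sensitivity = sum(pred & labels == 1) / sum(labels == 1),
       specificity = sum(!pred & labels == 0) / sum(labels == 0))
}

#' Qualitative performance bands for AUC and TSS
#'
#' Labels each metric with the conventional bands used for Southern Ocean
#' distribution models: AUC is "fair" in [0.7, 0.8) and "good" in [0.8, 1];
#' TSS is "fair" in [0.6, 0.7) and "good" in [0.7, 0.9]; anything below the
#' fair band is "poor". Lower bounds are inclusive.
#'
#' @param auc,tss metric values.
#' @return named character vector c(auc = ..., tss = ...).
#' @export
classifyPerformance <- function(auc, tss) {
  aucBand <- if (auc >= 0.8) "good" else if (auc >= 0.7) "fair" else "poor"
  tssBand <- if (tss >= 0.7) "good" else if (tss >= 0.6) "fair" else "poor"
  c(auc = aucBand, tss = tssBand)
}

#' Highest posterior density interval
#'
#' The shortest contiguous window of the sorted draws containing
#' ceiling(mass * n) draws (smallest starting index on ties), and whether
#' that interval excludes zero — the significance rule applied to residual
#' correlations at mass 0.99.
#'
#' @param samples numeric posterior draws.
#' @param mass interval probability mass (default 0.99).
#' @return list(lower, upper, significant).
#' @export
hpdInterval <- function(samples, mass = 0.99) {
  n <- length(samples)
  if (n < 1) stopf("empty draws")
  if (n == 1) return(list(lower = samples, upper = samples,
                          significant = samples != 0))
  s <- sort(samples)
  k <- min(n, max(1, ceiling(mass * n)))
  starts <- seq_len(n - k + 1)
  widths <- s[starts + k - 1] - s[starts]
  i <- which.min(widths)  # which.min returns the first (smallest start) tie
  lo <- s[i]; hi <- s[i + k - 1]
  list(lower = lo, upper = hi, significant = lo > 0 || hi < 0)
}
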