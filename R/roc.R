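#' ROC curve with exact counts
#'
#' Builds the receiver operating characteristic of a score-vs-binary-label
#' classification. Candidate thresholds are the midpoints between sorted
#' unique scores plus -Inf/+Inf sentinels; at threshold `t` an item is called
#' positive when its score exceeds `t`. Counts (TP, FP, TN, FN) are exact at
#' every threshold; `TPR = TP / (TP + FN)` and `FPR = FP / (FP + TN)`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return A `roc_curve` data frame: `threshold`, `TP`, `FP`, `TN`, `FN`,
#'   `TPR`, `FPR`, ordered by increasing threshold.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  # positives called at threshold t: score > t
  s_pos <- sort(scores[labels == 1L])
  s_neg <- sort(scores[labels == 0L])
  TP <- n_pos - findInterval(thr, s_pos)        # count of s_pos > t
  FP <- n_neg - findInterval(thr, s_neg)
  FN <- n_pos - TP
  TN <- n_neg - FP
  out <- data.frame(threshold = thr, TP = TP, FP = FP, TN = TN, FN = FN,
                    TPR = TP / n_pos, FPR = FP / n_neg)
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' ROC-optimal threshold by corner distance
#'
#' Chooses the threshold minimizing the Euclidean distance of the operating
#' point to the ideal (FPR, TPR) = (0, 1) corner,
#' `sqrt(FPR^2 + (1 - TPR)^2)`. Ties go to the larger threshold (fewer false
#' positives).
#'
#' @param curve A [roc_curve()].
#' @return List: `tau`, `corner_distance`, `TPR`, `FPR` at the optimum.
#' @export
optimal_threshold <- function(curve) {
  d <- sqrt(curve$FPR^2 + (1 - curve$TPR)^2)
  best <- max(which(d == min(d)))  # curve ordered by increasing threshold
  list(tau = curve$threshold[best], corner_distance = d[best],
       TPR = curve$TPR[best], FPR = curve$FPR[best])
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with tie correction; used for feature
#' ranking.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels, both classes present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
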