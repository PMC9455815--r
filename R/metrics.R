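#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative; ties count one half (average-rank / Mann-Whitney
#' convention). Undefined (NA) when either class is empty.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = annotated interaction).
#' @return Value in \[0, 1\], or `NA` if degenerate.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  np <- sum(labels)
  nn <- length(labels) - np
  if (np == 0 || nn == 0) {
    return(NA_real_)
  }
  r <- rank(scores) # average ranks for ties
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated average precision: the mean, over positives, of the
#' precision at each positive's rank. Ranking is deterministic (score
#' descending, then original order). NA when there are no positives.
#'
#' @inheritParams auroc
#' @return Value in (0, 1\], or `NA` without positives.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  np <- sum(labels)
  if (np == 0) {
    return(NA_real_)
  }
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  prec <- cumsum(y) / seq_along(y)
  sum(prec[y == 1]) / np
}

#' Boltzmann-enhanced discrimination of ROC (BEDROC)
#'
#' Early-recognition metric weighting the rank of each positive by an
#' exponential decay \eqn{e^{-\alpha r / N}} and normalising the resulting
#' robust initial enhancement to \[0, 1\]. Higher `alpha` focuses the metric
#' on the earliest part of the ranking; the conventional virtual-screening
#' setting is `alpha = 20`. NA when either class is empty.
#'
#' @inheritParams auroc
#' @param alpha Exponential decay parameter (default 20). Distinct from the
#'   similarity cutoff also called alpha elsewhere in the package.
#' @return Value in \[0, 1\], or `NA` if degenerate.
#' @export
bedroc <- function(scores, labels, alpha = 20) {
  labels <- as.integer(labels > 0)
  n <- length(labels)
  np <- sum(labels)
  if (np == 0 || np == n) {
    return(NA_real_)
  }
  ord <- order(-scores, seq_along(scores))
  ranks <- which(labels[ord] == 1)
  ra <- np / n
  rie <- sum(exp(-alpha * ranks / n)) /
    (np / n * (1 - exp(-alpha)) / (exp(alpha / n) - 1))
  rie_min <- (1 - exp(alpha * ra)) / (ra * (1 - exp(alpha)))
  rie_max <- (1 - exp(-alpha * ra)) / (ra * (1 - exp(-alpha)))
  (rie - rie_min) / (rie_max - rie_min)
}

#' Precision and recall of the top-k predictions
#'
#' Cuts the ranked list at `k` and reports the fraction of retrieved
#' positives over `k` (precision; the denominator stays `k` even when fewer
#' predictions exist) and over all positives (recall). Only targets with a
#' strictly positive score count as retrieved: a zero score means the
#' spreading process makes no prediction for that target, so an unreachable
#' target is never credited as a retrieval.
#'
#' @inheritParams auroc
#' @param k Cut-off rank (default 20).
#' @return A named list with elements `precision` and `recall` (`recall` is
#'   `NA` without positives).
#' @export
precision_recall_at_k <- function(scores, labels, k = 20) {
  if (k < 1) abort("`k` must be >= 1")
  labels <- as.integer(labels > 0)
  ord <- order(-scores, seq_along(scores))
  retrieved <- ord[scores[ord] > 0]
  top <- head(retrieved, k)
  hits <- sum(labels[top])
  list(
    precision = hits / k,
    recall = if (sum(labels) == 0) NA_real_ else hits / sum(labels)
  )
}

#' Maximum-threshold binary classification metrics
#'
#' Sweeps every distinct score as a decision threshold (predicted positive
#' iff score >= threshold, plus the trivial reject-all threshold), computes
#' Matthews correlation coefficient, F1 and balanced accuracy at each, and
#' returns the maximum of each metric independently. Empty-denominator cases (MCC, F1) are defined as 0. NA
#' for all three when either class is empty.
#'
#' @inheritParams auroc
#' @return A named list with elements `mcc`, `f1` and `bacc`.
#' @export
max_threshold_metrics <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  np <- sum(labels)
  nn <- length(labels) - np
  if (np == 0 || nn == 0) {
    return(list(mcc = NA_real_, f1 = NA_real_, bacc = NA_real_))
  }
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  s <- scores[ord]
  # threshold at each distinct score: predicted positive = all ranks up to
  # the last occurrence of that score
  cut <- which(!duplicated(s, fromLast = TRUE)) # last index of each block
  cut <- c(0, cut) # plus the reject-all classifier (threshold above all scores)
  tp <- c(0, cumsum(y))[cut + 1]
  fp <- cut - tp
  fn <- np - tp
  tn <- nn - fp
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- ifelse(mcc_den == 0, 0, (tp * tn - fp * fn) / mcc_den)
  f1_den <- 2 * tp + fp + fn
  f1 <- ifelse(f1_den == 0, 0, 2 * tp / f1_den)
  bacc <- (tp / np + tn / nn) / 2
  list(mcc = max(mcc), f1 = max(f1), bacc = max(bacc))
}

#' Evaluate a labelled prediction ranking with all eight metrics
#'
#' Computes the full metric panel used for benchmarking: overall ranking
#' quality (AuROC, AuPRC), early recognition (BEDROC, P@k, R@k) and maximum
#' binary prediction performance (max MCC, max F1, max balanced accuracy).
#' Targets outside `mask` (e.g. targets disconnected from the training
#' network, which can never be predicted) are dropped before any
#' calculation and never affect the values.
#'
#' @inheritParams auroc
#' @param mask Logical vector of evaluable targets (default all).
#' @param k Rank cut for P@k / R@k (default 20).
#' @param bedroc_alpha Decay for [bedroc()] (default 20).
#' @return A one-row tibble with the metric values plus `n_pos`, `n_neg`.
#' @export
evaluate_ranking <- function(scores, labels, mask = NULL, k = 20, bedroc_alpha = 20) {
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  if (!is.null(mask)) {
    scores <- scores[mask]
    labels <- labels[mask]
  }
  labels <- as.integer(labels > 0)
  pr <- precision_recall_at_k(scores, labels, k)
  mx <- max_threshold_metrics(scores, labels)
  tibble(
    n_pos = sum(labels),
    n_neg = length(labels) - sum(labels),
    auroc = auroc(scores, labels),
    auprc = auprc(scores, labels),
    bedroc = bedroc(scores, labels, bedroc_alpha),
    p_at_k = pr$precision,
    r_at_k = pr$recall,
    mcc_max = mx$mcc,
    f1_max = mx$f1,
    bacc_max = mx$bacc
  )
}
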