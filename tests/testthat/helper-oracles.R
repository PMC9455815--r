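# Independent per-node / brute-force oracles. These deliberately use plain
# loops over nodes, pairs and thresholds so they share no code with the
# vectorised implementations they check.

# Two-round diffusion on the F-D-T graph, one node at a time.
spread_oracle <- function(fd, dt, q, propagation = "weighted") {
  nf <- nrow(fd)
  nd <- ncol(fd)
  nt <- ncol(dt)
  res_d <- numeric(nd)
  res_t <- numeric(nt)
  res_f_new <- numeric(nf)
  for (f in seq_len(nf)) {
    if (q[f] == 0) next
    nbr <- which(fd[f, ] > 0)
    if (!length(nbr)) next
    w <- if (propagation == "binary") rep(1, length(nbr)) else fd[f, nbr]
    for (j in seq_along(nbr)) {
      res_d[nbr[j]] <- res_d[nbr[j]] + q[f] * w[j] / sum(w)
    }
  }
  for (d in seq_len(nd)) {
    if (res_d[d] == 0) next
    nbr_f <- which(fd[, d] > 0)
    nbr_t <- which(dt[d, ] > 0)
    w_f <- if (propagation == "binary") rep(1, length(nbr_f)) else fd[nbr_f, d]
    w_t <- if (propagation == "binary") rep(1, length(nbr_t)) else dt[d, nbr_t]
    tot <- sum(w_f) + sum(w_t)
    if (tot == 0) next
    for (j in seq_along(nbr_f)) {
      res_f_new[nbr_f[j]] <- res_f_new[nbr_f[j]] + res_d[d] * w_f[j] / tot
    }
    for (j in seq_along(nbr_t)) {
      res_t[nbr_t[j]] <- res_t[nbr_t[j]] + res_d[d] * w_t[j] / tot
    }
  }
  list(target = res_t, feature = res_f_new)
}

# Bipartite NBI for one query drug, one node at a time.
nbi_oracle <- function(A, drug_row) {
  nd <- nrow(A)
  nt <- ncol(A)
  res_t <- A[drug_row, ] # one unit per annotated target
  res_d <- numeric(nd)
  for (t in seq_len(nt)) {
    if (res_t[t] == 0) next
    nbr <- which(A[, t] > 0)
    for (d in nbr) res_d[d] <- res_d[d] + res_t[t] / length(nbr)
  }
  out <- numeric(nt)
  for (d in seq_len(nd)) {
    if (res_d[d] == 0) next
    nbr <- which(A[d, ] > 0)
    for (t in nbr) out[t] <- out[t] + res_d[d] / length(nbr)
  }
  out
}

# AuROC by explicit pairwise concordance counting, ties worth one half.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) {
    return(NA_real_)
  }
  tot <- 0
  for (p in pos) {
    for (n in neg) {
      tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# BEDROC by direct summation of the RIE formula, normalised between the
# directly summed best and worst rank placements.
bedroc_oracle <- function(scores, labels, alpha = 20) {
  n <- length(labels)
  np <- sum(labels)
  if (np == 0 || np == n) {
    return(NA_real_)
  }
  ord <- order(-scores, seq_along(scores))
  ranks <- which(labels[ord] == 1)
  rie_of <- function(r) {
    (sum(exp(-alpha * r / n)) / np) /
      ((1 / n) * (1 - exp(-alpha)) / (exp(alpha / n) - 1))
  }
  rie <- rie_of(ranks)
  rie_best <- rie_of(seq_len(np))
  rie_worst <- rie_of(seq(n - np + 1, n))
  (rie - rie_worst) / (rie_best - rie_worst)
}

# Maximum threshold metrics by exhaustive enumeration over all thresholds
# (each distinct score plus one above the maximum), counting the confusion
# matrix element by element.
maxthresh_oracle <- function(scores, labels) {
  thr <- c(sort(unique(scores)), max(scores) + 1)
  best <- c(mcc = -Inf, f1 = -Inf, bacc = -Inf)
  for (th in thr) {
    tp <- fp <- tn <- fn <- 0
    for (i in seq_along(scores)) {
      pred <- scores[i] >= th
      if (pred && labels[i] == 1) tp <- tp + 1
      if (pred && labels[i] == 0) fp <- fp + 1
      if (!pred && labels[i] == 0) tn <- tn + 1
      if (!pred && labels[i] == 1) fn <- fn + 1
    }
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    bacc <- (tp / (tp + fn) + tn / (tn + fp)) / 2
    best["mcc"] <- max(best["mcc"], mcc)
    best["f1"] <- max(best["f1"], f1)
    best["bacc"] <- max(best["bacc"], bacc)
  }
  best
}

# Random tripartite blocks where every feature node has at least one drug
# edge (so no initial resource can sit on a degree-0 node).
random_tripartite <- function(nf, nd, nt, seed, weighted = TRUE) {
  set.seed(seed)
  fd <- matrix(runif(nf * nd) * (runif(nf * nd) < 0.5), nf, nd)
  if (!weighted) fd <- (fd > 0) * 1
  for (f in seq_len(nf)) {
    if (all(fd[f, ] == 0)) fd[f, sample(nd, 1)] <- if (weighted) runif(1, 0.1, 1) else 1
  }
  dt <- matrix((runif(nd * nt) < 0.4) * 1, nd, nt)
  rownames(fd) <- paste0("f", seq_len(nf))
  colnames(fd) <- rownames(dt) <- paste0("d", seq_len(nd))
  colnames(dt) <- paste0("t", seq_len(nt))
  list(fd = fd, dt = dt)
}

# Long prediction tibble -> named score vector in target order.
score_vector <- function(preds, query, targets) {
  p <- preds[preds$query == query, ]
  setNames(p$score[match(targets, p$target)], targets)
}
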