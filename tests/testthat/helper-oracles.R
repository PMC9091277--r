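# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: entropy by
# explicit term-by-term summation, AUC by pair counting, PR and Youden by
# per-cut confusion matrices, Fisher by full enumeration over fixed margins.

brute_selv <- function(frequencies, base = exp(1)) {
  total <- 0
  for (f in frequencies) {
    if (f > 0 && f < 1) total <- total - f * log(f, base = base)
  }
  total
}

# Mann-Whitney pair counting: P(pathogenic score > neutral score) + ties/2
brute_auc <- function(scores, labels, orientation = "higher_is_pathogenic") {
  s <- if (orientation == "lower_is_pathogenic") -scores else scores
  sp <- s[labels == 1]
  sn <- s[labels == 0]
  cmp <- outer(sp, sn, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# exhaustive enumeration over every distinct cut, confusion matrix from
# scratch at each; step-wise (average precision) area
brute_pr_auc <- function(scores, labels, orientation = "higher_is_pathogenic") {
  s <- if (orientation == "lower_is_pathogenic") -scores else scores
  cuts <- sort(unique(s), decreasing = TRUE)
  P <- sum(labels == 1)
  area <- 0
  recall_prev <- 0
  for (t in cuts) {
    called <- s >= t
    tp <- sum(called & labels == 1)
    fp <- sum(called & labels == 0)
    area <- area + (tp / P - recall_prev) * (tp / (tp + fp))
    recall_prev <- tp / P
  }
  area
}

# exhaustive Youden search over midpoint candidates with the inclusive rule
brute_youden <- function(scores, labels, orientation) {
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf) else c(-Inf, Inf)
  best <- -Inf
  for (t in cand) {
    called <- if (orientation == "lower_is_pathogenic") scores <= t else scores >= t
    sens <- sum(called & labels == 1) / sum(labels == 1)
    spec <- sum(!called & labels == 0) / sum(labels == 0)
    best <- max(best, sens + spec - 1)
  }
  best
}

# sup |ECDF_a - ECDF_b| swept over every observed value
brute_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# two-sided Fisher p by enumerating all tables with the observed margins;
# same tie tolerance as the conditional test (1 + 1e-7)
brute_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1))
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# stratified paired bootstrap of the AUC difference (both scores resampled
# on the same observations)
bootstrap_auc_diff_var <- function(scores_a, scores_b, labels, reps = 2000) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  diffs <- vapply(seq_len(reps), function(r) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    brute_auc(scores_a[idx], labels[idx]) - brute_auc(scores_b[idx], labels[idx])
  }, numeric(1))
  stats::var(diffs)
}

# small labeled instance with continuous scores and a tunable signal
random_instance <- function(n_pos, n_neg, signal = 1, ties = FALSE) {
  scores <- c(stats::rnorm(n_pos, mean = signal), stats::rnorm(n_neg))
  if (ties) scores <- round(scores, 1)
  list(scores = scores, labels = rep(c(1, 0), c(n_pos, n_neg)))
}
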