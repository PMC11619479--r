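# Independent brute-force oracles used to check the analytic implementations.

# AUC as the Mann-Whitney concordance probability over all pos/neg pairs,
# ties counted one half.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n)))
}

# Largest observed cutoff whose sensitivity (score >= cutoff) meets the target.
cutoff_bruteforce <- function(scores, labels, target) {
  cand <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  for (c in cand) {
    if (sum(scores >= c & labels == 1) / n_pos >= target / 100) return(c)
  }
  NA_real_
}

# Youden-optimal ratio cutoff by exhaustive scan over adjacent midpoints,
# GN called when ratio <= cutoff; ties to higher sensitivity.
youden_bruteforce <- function(ratios, gram) {
  s <- sort(unique(ratios))
  cand <- (head(s, -1) + tail(s, -1)) / 2
  sens <- sapply(cand, function(c) mean(ratios[gram == "GN"] <= c))
  spec <- sapply(cand, function(c) mean(ratios[gram == "GP"] > c))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  list(cutoff = cand[best][which.max(sens[best])], j = max(j))
}

# A small flagged cohort joined for downstream stages.
make_test_cohort <- function(n = 800, seed = 7, ...) {
  simulate_cohort(make_default_config(seed = seed, n_samples = n, ...))
}
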