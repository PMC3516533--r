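# Independent oracles used by both the module tests and the acceptance
# suite. Each is a literal, brute-force transcription of the definition it
# checks, kept free of any package internals.

# exhaustive pair-counting AUC
auc_pairwise <- function(scores, labels) {
  sp <- scores[labels == "present"]
  sa <- scores[labels == "absent"]
  tot <- 0
  for (x in sp) for (y in sa) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(sp) * length(sa))
}

# literal piecewise environmental-similarity component
mess_oracle <- function(ref, p) {
  lo <- min(ref); hi <- max(ref)
  f <- 100 * sum(ref < p) / length(ref)
  if (f == 0) 100 * (p - lo) / (hi - lo)
  else if (f <= 50) 2 * f
  else if (f < 100) 2 * (100 - f)
  else 100 * (hi - p) / (hi - lo)
}

# exhaustive scan for the mean-probability threshold
mean_prob_oracle <- function(p) {
  m <- mean(p)
  cand <- sort(unique(p))
  best <- cand[1]; best_d <- Inf
  for (t in cand) {
    d <- abs(mean(p >= t) - m)
    if (d < best_d) { best <- t; best_d <- d }
  }
  best
}
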