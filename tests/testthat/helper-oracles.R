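# Naive step-up FDR oracle, written directly from the definition:
# q_(i) = min(1, min_{j >= i} p_(j) * n / j), independent of stats::p.adjust.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(n)
  for (i in seq_len(n)) q_sorted[i] <- min(1, ps[i:n] * n / (i:n))
  q <- numeric(n); q[o] <- q_sorted
  q
}

# F1 of a recovered gene set against a truth set.
f1_score <- function(called, truth) {
  tp <- length(intersect(called, truth))
  if (tp == 0) return(0)
  precision <- tp / length(called)
  recall <- tp / length(truth)
  2 * precision * recall / (precision + recall)
}
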