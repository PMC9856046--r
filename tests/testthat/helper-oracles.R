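# independent brute-force oracles used by several test files

# exhaustive threshold-sweep q-value oracle for target-decoy FDR
sweep_q_oracle <- function(score, is_decoy) {
  vapply(score, function(s) {
    cand <- score[score <= s]
    min(vapply(unique(cand), function(t) {
      tt <- sum(!is_decoy & score >= t)
      dd <- sum(is_decoy & score >= t)
      if (tt == 0) 1 else min(1, dd / tt)
    }, numeric(1)))
  }, numeric(1))
}

# direct hypergeometric-tail summation
hyper_tail_oracle <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# textbook step-up Benjamini-Hochberg
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}
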