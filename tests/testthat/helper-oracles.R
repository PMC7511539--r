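# Independent brute-force oracles used by the scoring and statistics tests.
# These deliberately avoid the package's own algorithms.

# Maximum common-subsequence length by exhaustive enumeration: every
# subsequence of `a` is tested for subsequence containment in `b`.
oracle_lcs_length <- function(a, b) {
  is_subseq <- function(s, v) {
    if (!length(s)) return(TRUE)
    j <- 1L
    for (x in v) {
      if (x == s[j]) {
        j <- j + 1L
        if (j > length(s)) return(TRUE)
      }
    }
    FALSE
  }
  best <- 0L
  n <- length(a)
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) > best && is_subseq(a[idx], b)) best <- length(idx)
  }
  best
}

# Exact two-sided Wilcoxon rank-sum p-value and Mann-Whitney W by complete
# enumeration of all group assignments of the pooled sample (mid-ranks).
oracle_wilcoxon <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  W_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  Ws <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- mean(Ws)
  p <- mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
  list(W = W_obs, p = min(p, 1))
}

# A metronomically uniform rendition of a melody at performance tempo `bpm`.
uniform_tempo_perf <- function(melody, bpm) {
  performance(melody$pitches, melody_onsets(melody) * melody$tempo_bpm / bpm)
}
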