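# Brute-force metric oracles, independent of the implementations under test.

oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

oracle_ap_stepsum <- function(scores, labels) {
  ord <- order(-scores)
  y <- labels[ord]
  hits <- 0; s <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1) {
      hits <- hits + 1
      s <- s + hits / i
    }
  }
  s / sum(labels)
}

oracle_youden_scan <- function(scores, labels) {
  best <- -Inf
  for (th in sort(unique(c(scores - 1e-9, scores + 1e-9)))) {
    J <- mean(scores[labels == 1] > th) - mean(scores[labels == 0] > th)
    if (J > best) best <- J
  }
  best
}

oracle_ppv <- function(scores, labels, k) {
  mean(labels[order(-scores)][seq_len(k)])
}
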