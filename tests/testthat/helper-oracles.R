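# Independent brute-force oracles, deliberately naive and separate from the
# implementations they check.

aucBrute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

maxTssBrute <- function(scores, labels) {
  cands <- c(sort(unique(scores)), max(scores) + 1)
  max(vapply(cands, function(th) tssAt(scores, labels, th), numeric(1)))
}

hpdBrute <- function(x, mass) {
  s <- sort(x); n <- length(s)
  k <- min(n, max(1, ceiling(mass * n)))
  best <- c(Inf, NA, NA)
  for (i in seq_len(n - k + 1)) {
    w <- s[i + k - 1] - s[i]
    if (w < best[1]) best <- c(w, s[i], s[i + k - 1])
  }
  best[2:3]
}
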