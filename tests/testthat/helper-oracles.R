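# Independent brute-force oracles used to cross-check the statistical routes.

# Two-sided Fisher exact p for the 2x2 table [[a, b], [c, d]] by full
# hypergeometric enumeration over all tables with the observed margins:
# sum of probabilities of tables no more probable than the observed one.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  xs <- max(0, k - r2):min(r1, k)
  probs <- choose(r1, xs) * choose(r2, k - xs) / choose(r1 + r2, k)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-07)])
}

# One-sided over-representation p for a 2x2 table by enumeration of the
# upper tail of the hypergeometric distribution.
hyper_upper_oracle <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  xs <- a:min(r1, k)
  sum(choose(r1, xs) * choose(r2, k - xs) / choose(r1 + r2, k))
}

# Exact one-sided Mann-Whitney p ("x smaller") by enumeration of all rank
# arrangements of the pooled sample (no ties assumed).
mw_less_oracle <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  u_all <- apply(combos, 2, function(idx) sum(ranks[idx]) - m * (m + 1) / 2)
  mean(u_all <= u_obs)
}

# Benjamini-Hochberg step-up by its definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}
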