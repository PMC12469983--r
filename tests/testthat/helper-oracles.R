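# Independent oracles, deliberately written as naive direct computations.

# Loop-based diversity oracle (no vectorized reuse of the implementation).
oracle_diversity <- function(n) {
  N <- 0; for (x in n) N <- N + x
  S <- length(n)
  H <- 0; ss <- 0
  for (x in n) { p <- x / N; H <- H - p * log(p); ss <- ss + p * p }
  f1 <- 0; f2 <- 0
  for (x in n) { if (x == 1) f1 <- f1 + 1; if (x == 2) f2 <- f2 + 1 }
  chao1 <- S + f1 * (f1 - 1) / (2 * (f2 + 1))
  rare <- n[n <= 10]; Nr <- sum(rare); Sr <- length(rare)
  if (Sr == 0) ace <- S
  else {
    Ca <- 1 - f1 / Nr
    if (Ca == 0 || Nr <= 1) ace <- chao1
    else {
      s2 <- 0
      for (k in 1:10) s2 <- s2 + k * (k - 1) * sum(rare == k)
      g2 <- max(Sr * s2 / (Ca * Nr * (Nr - 1)) - 1, 0)
      ace <- (S - Sr) + Sr / Ca + f1 / Ca * g2
    }
  }
  c(S_obs = S, H = H, inv_simpson = 1 / ss, gini_simpson = 1 - ss,
    norm_entropy = if (S > 1) H / log(S) else 0, chao1 = chao1, ace = ace)
}

# Memoized recursive edit-distance oracle.
lev_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  memo <- matrix(NA_integer_, length(ca) + 1, length(cb) + 1)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- if (i == 0) j
    else if (j == 0) i
    else min(rec(i - 1, j) + 1, rec(i, j - 1) + 1,
             rec(i - 1, j - 1) + (ca[i] != cb[j]))
    memo[i + 1, j + 1] <<- v
    v
  }
  rec(length(ca), length(cb))
}
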