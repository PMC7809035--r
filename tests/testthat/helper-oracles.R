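# Independent oracles used to cross-check the package's implementations.

# Hypergeometric upper tail by exhaustive enumeration of the pmf.
hyper_upper_enum <- function(N, K, n, k) {
  js <- k:min(n, K)
  if (length(js) == 0L || k > min(n, K)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Slow proximal-gradient maximizer of
# log det(Omega) - tr(S Omega) - lambda * sum_offdiag |Omega_ij|,
# independent of the coordinate-descent route.
pg_glasso <- function(S, lambda, iters = 20000, step = 0.05) {
  p <- nrow(S)
  Omega <- diag(1 / diag(S))
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  for (i in seq_len(iters)) {
    G <- solve(Omega) - S
    t_i <- step
    repeat {
      cand <- Omega + t_i * G
      off <- soft(cand, t_i * lambda)
      diag(off) <- diag(cand)          # diagonal unpenalized
      cand <- (off + t(off)) / 2
      ev <- min(eigen(cand, symmetric = TRUE, only.values = TRUE)$values)
      if (ev > 1e-10) break
      t_i <- t_i / 2
    }
    Omega <- cand
  }
  Omega
}

# Normal-equations OLS with classical t-tests, no lm().
ols_oracle <- function(y, X) {
  X <- cbind(1, X)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  list(beta = drop(beta), se = se, t = drop(tval),
       p = 2 * pt(-abs(drop(tval)), df))
}

# Brute-force scan for GWAS-proximal genes.
gwas_brute <- function(intervals, probes, window = 50000, alpha = 0.05) {
  flagged <- character(0)
  for (i in seq_len(nrow(intervals))) {
    g <- intervals[i, ]
    ok <- probes$chrom == g$chrom & probes$p < alpha &
      probes$pos >= g$start - window & probes$pos <= g$end + window
    if (any(ok)) flagged <- c(flagged, g$gene)
  }
  flagged
}
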