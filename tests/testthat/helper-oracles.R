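# Independent oracles used across the suite.

# Two-sided Fisher exact p by direct hypergeometric enumeration: sum the
# probabilities of all tables (margins fixed) no more likely than the
# observed one.  a,b = significant in/out of unit; c,d = not significant.
oracle_fisher_p <- function(a, b, c, d) {
  C1 <- a + c
  C2 <- b + d
  R1 <- a + b
  x <- max(0, R1 - C2):min(R1, C1)
  pr <- dhyper(x, C1, C2, R1)
  sum(pr[pr <= dhyper(a, C1, C2, R1) * (1 + 1e-7)])
}

# Two-sample KS statistic by brute-force ECDF sweep over all observed values.
oracle_ks_stat <- function(x, y) {
  g <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(g) - ecdf(y)(g)))
}

# Pillai's trace for a two-group comparison with no covariates, computed
# from explicit group means (independent of the package's QR path).
oracle_pillai <- function(Y, grp) {
  # Y: samples x responses
  lv <- unique(grp)
  centered <- Y
  E <- matrix(0, ncol(Y), ncol(Y))
  gm <- colMeans(Y)
  H <- matrix(0, ncol(Y), ncol(Y))
  for (g in lv) {
    rows <- grp == g
    m <- colMeans(Y[rows, , drop = FALSE])
    E <- E + crossprod(sweep(Y[rows, , drop = FALSE], 2, m))
    H <- H + sum(rows) * tcrossprod(m - gm)
  }
  sum(diag(H %*% solve(H + E)))
}

# Unadjusted Rand index between two labelings.
rand_index <- function(x, y) {
  n <- length(x)
  idx <- combn(n, 2)
  sx <- x[idx[1, ]] == x[idx[2, ]]
  sy <- y[idx[1, ]] == y[idx[2, ]]
  mean(sx == sy)
}
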