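# Independent oracles used across tests. These deliberately reimplement
# the quantities under test by brute force or enumeration.

# Full-matrix semi-global Levenshtein DP (free gaps at both locus ends).
oracle_semiglobal_distance <- function(read, locus) {
  r <- strsplit(read, "")[[1]]
  l <- strsplit(locus, "")[[1]]
  n <- length(r)
  m <- length(l)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- as.integer(r[i] != l[j] || r[i] == "N" || l[j] == "N")
      D[i + 1, j + 1] <- min(D[i, j] + sub, D[i, j + 1] + 1L, D[i + 1, j] + 1L)
    }
  }
  min(D[n + 1, ])
}

# Two-sided Fisher p by full enumeration of tables with the observed
# margins, summing probabilities <= observed (with fisher.test's relative
# tolerance for ties).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(xs, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating all group-A rank subsets.
oracle_mann_whitney_p <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(idx) sum(seq_len(nx + ny)[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Log marginal likelihood of counts under a uniform PSI prior, by adaptive
# numerical integration (independent of the package's fixed-grid path).
# The integrand is rescaled by its mode to avoid underflow.
oracle_log_marginal <- function(k, l, c_inc = 1, c_exc = 1) {
  qhat <- if (k + l == 0) 0.5 else k / (k + l)
  log_mode <- (if (k > 0) k * log(qhat) else 0) +
    (if (l > 0) l * log(1 - qhat) else 0)
  f <- function(psi) {
    q <- psi * c_inc / (psi * c_inc + (1 - psi) * c_exc)
    lf <- 0 * psi + (if (k == 0) 0 else k * log(q)) +
      (if (l == 0) 0 else l * log1p(-q))
    exp(lf - log_mode)
  }
  log(stats::integrate(f, 0, 1, rel.tol = 1e-10)$value) + log_mode
}

oracle_log_bf <- function(k1, l1, k2, l2) {
  oracle_log_marginal(k1, l1) + oracle_log_marginal(k2, l2) -
    oracle_log_marginal(k1 + k2, l1 + l2)
}
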