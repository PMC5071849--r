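# Independent brute-force oracles. These re-derive each statistic by naive
# per-locus loops and textbook formulas, deliberately sharing no code with
# the package implementation.

# D statistic by explicit loop; quartet columns (W, X, Y, Z)
oracle_d <- function(f) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(f))) {
    w <- f[i, 1]; x <- f[i, 2]; y <- f[i, 3]; z <- f[i, 4]
    if (anyNA(c(w, x, y, z))) next
    num <- num + (x - w) * (y - z)
    den <- den + (w + x - 2 * w * x) * (y + z - 2 * y * z)
  }
  num / den
}

# delete-one-block jackknife SE for equal informative-locus blocks:
# SE^2 = (g-1)/g * sum((theta_j - mean(theta_j))^2)
oracle_jackknife_se_equal <- function(f, block_size) {
  n <- nrow(f)
  g <- n %/% block_size
  stopifnot(g * block_size == n)
  theta <- vapply(seq_len(g), function(j) {
    keep <- rep(TRUE, n)
    keep[((j - 1) * block_size + 1):(j * block_size)] <- FALSE
    oracle_d(f[keep, , drop = FALSE])
  }, 1)
  sqrt((g - 1) / g * sum((theta - mean(theta))^2))
}

# f4 by explicit loop; columns (A, O, X, C)
oracle_f4 <- function(f) {
  tot <- 0; used <- 0
  for (i in seq_len(nrow(f))) {
    v <- f[i, ]
    if (anyNA(v)) next
    tot <- tot + (v[1] - v[2]) * (v[3] - v[4])
    used <- used + 1
  }
  tot / used
}

# hypergeometric upper tail by direct log-space summation
oracle_hyper_upper <- function(N, K, n, k) {
  if (k == 0) return(1)
  x <- k:min(K, n)
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

# full hypergeometric pmf over its support
oracle_hyper_pmf <- function(N, K, n) {
  x <- max(0, n - (N - K)):min(K, n)
  exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
}

# weighted ridge regression with unpenalized intercept by accumulating the
# normal equations entry by entry
oracle_ridge_beta <- function(X, y, w, lambda) {
  p <- ncol(X) + 1
  A <- matrix(0, p, p)
  b <- numeric(p)
  for (i in seq_len(nrow(X))) {
    xi <- c(1, X[i, ])
    for (r in seq_len(p)) {
      for (s in seq_len(p)) A[r, s] <- A[r, s] + w[i] * xi[r] * xi[s]
      b[r] <- b[r] + w[i] * xi[r] * y[i]
    }
  }
  for (r in 2:p) A[r, r] <- A[r, r] + lambda
  solve(A, b)
}

# site-pattern classification by per-locus enumeration for matrices with a
# deterministic representative (populations fixed for one allele per locus)
oracle_patterns <- function(states) {
  # states: n x 4 over {"A","B",NA}; columns (P1, P2, P3, O)
  out <- c(BBAA = 0, ABBA = 0, BABA = 0, informative = 0)
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    if (anyNA(s)) next
    d <- s[1:3] != s[4]
    if (sum(d) != 2) next
    out["informative"] <- out["informative"] + 1
    if (d[1] && d[2]) out["BBAA"] <- out["BBAA"] + 1
    if (d[2] && d[3]) out["ABBA"] <- out["ABBA"] + 1
    if (d[1] && d[3]) out["BABA"] <- out["BABA"] + 1
  }
  out
}

# allele frequency for one locus x population by direct tally:
# calls are alt-allele counts (diploid) or 2 * alt indicator (pseudo-haploid)
oracle_freq <- function(calls, per_call) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) return(NA_real_)
  alt <- if (per_call == 2) sum(calls) else sum(calls) / 2
  alt / (length(calls) * per_call)
}
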