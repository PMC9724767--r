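# Independent oracles used to cross-check the package implementations.
# Each reimplements its quantity from the definition, without touching the
# code paths under test.

# Definition-based BH step-up: sort, scale by n/rank, enforce monotonicity
# from the largest rank down, cap at 1, restore input order.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  raw <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(raw)))
  pmin(adj, 1)[order(o)]
}

# Direct numeric solution of the variance-prior moment equations, by
# minimisation on a log grid rather than root bracketing.
prior_oracle <- function(s2, df) {
  z <- log(s2)
  excess <- stats::var(z) - trigamma(df / 2)
  bias <- digamma(df / 2) - log(df / 2)
  if (excess <= 0) return(list(d0 = Inf, s0_sq = exp(mean(z) - bias)))
  obj <- function(lh) (trigamma(exp(lh)) - excess)^2
  lh <- stats::optimize(obj, c(log(1e-8), log(1e6)), tol = 1e-14)$minimum
  half <- exp(lh)
  list(d0 = 2 * half,
       s0_sq = exp(mean(z) - bias + digamma(half) - log(half)))
}

# Brute-force greedy correlation pruning over a correlation matrix.
prune_oracle <- function(R, thr) {
  kept <- integer(0)
  for (i in seq_len(nrow(R))) {
    if (!length(kept) || all(abs(R[i, kept]) < thr)) kept <- c(kept, i)
  }
  kept
}

# Brute-force double-loop Euclidean distances between columns.
dist_oracle <- function(m) {
  n <- ncol(m)
  D <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((m[, i] - m[, j])^2))
  D
}

# Independent Torgerson MDS: double-centre, eigendecompose, scale, apply
# the same sign convention.
mds_oracle <- function(D, k) {
  n <- nrow(D)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% D^2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  co <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  for (j in seq_len(k)) {
    i <- which.max(abs(co[, j]))
    if (co[i, j] < 0) co[, j] <- -co[, j]
  }
  co
}
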