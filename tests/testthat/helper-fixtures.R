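# Fixtures are built in code; no data files.

std_markers <- function(n, p, seed = 1) {
  standardize_markers(simulate_markers(n, p, seed = seed), seed = seed)
}

# Independent brute-force linear kernel: explicit double loop over dot products.
oracle_linear_kernel <- function(X) {
  n <- nrow(X); p <- ncol(X)
  K <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(p)) s <- s + X[i, k] * X[j, k]
    K[i, j] <- s / p
  }
  K
}

# Exact posterior mean of (mu, u) for y = 1 mu + u + e with fixed unit
# variances and flat prior on mu: solve the joint normal equations.
oracle_gblup_mean <- function(y, K) {
  n <- length(y)
  Kinv <- solve(K + diag(1e-8, n))
  A <- rbind(c(n, rep(1, n)), cbind(1, Kinv + diag(n)))
  sol <- solve(A, c(sum(y), y))
  list(mu = sol[1], u = sol[-1])
}

# A small complete phenotype grid with genetic signal drawn through K.
toy_multienv <- function(n = 40, m = 2, p = 80, seed = 1) {
  X <- std_markers(n, p, seed = seed)
  K <- linear_kernel(X)
  UE <- 0.7 * (diag(m) * 0.4 + 0.6)
  sc <- simulation_scenario(n = n, m = m, p = p, UE_true = UE,
                            Sigma_true = rep(0.3, m), seed = seed)
  sim <- simulate_multienv_phenotypes(sc, K = K)
  list(X = X, K = K, table = sim$table, truth = sim$truth)
}
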