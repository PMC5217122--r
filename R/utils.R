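# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state afterwards
# so that model fits are reproducible without clobbering the session stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.symmetrize <- function(M) (M + t(M)) / 2

.is_symmetric <- function(M, tol = 1e-10) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol * max(1, max(abs(M)))
}

.check_pd <- function(M, name = "matrix", tol = 1e-8) {
  if (!.is_symmetric(M)) stop(name, " must be symmetric", call. = FALSE)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= -tol * max(abs(ev))) {
    stop(name, " is not positive definite (min eigenvalue ", signif(min(ev), 3), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Cholesky with a single jitter retry (1e-8 * mean diagonal), per the package's
# documented jitter policy for near-singular kernels.
.chol_jitter <- function(M, name = "matrix") {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    jit <- 1e-8 * mean(diag(M))
    if (!is.finite(jit) || jit <= 0) jit <- 1e-8
    ch <- tryCatch(chol(M + diag(jit, nrow(M))), error = function(e) NULL)
    if (is.null(ch)) stop("Cholesky of ", name, " failed even after jitter", call. = FALSE)
  }
  ch
}

# Eigendecomposition of a kernel with the documented jitter applied to the
# spectrum: negative eigenvalues are floored at zero and 1e-8 * mean(diag) is
# added, equivalent to a one-time diagonal jitter of the kernel itself.
.eigen_kernel <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  jit <- 1e-8 * mean(diag(K))
  if (!is.finite(jit) || jit <= 0) jit <- 1e-8
  list(vectors = e$vectors, values = pmax(e$values, 0) + jit)
}

# Round half away from zero (presentation rule for percent-change tables).
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Effective sample size via Geyer's initial positive sequence estimator.
.ess <- function(x) {
  x <- as.numeric(x)
  R <- length(x)
  if (R < 10 || stats::sd(x) == 0) return(R)
  lag_max <- min(R - 1L, 2000L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[-1]
  s <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    g <- rho[k] + rho[k + 1]
    if (!is.finite(g) || g <= 0) break
    s <- s + g
    k <- k + 2
  }
  max(1, min(R, R / (1 + 2 * s)))
}

.stopifnot_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < 0)
    stop(name, " must be a single non-negative integer", call. = FALSE)
  as.integer(x)
}
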