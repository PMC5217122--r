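# Multi-environment Kronecker models:
#   model 2:  y = mu + u + e,      u ~ N(0, UE (x) K),                e ~ N(0, Sigma (x) I)
#   model 3:  y = mu + u + f + e,  f ~ N(0, FE (x) I) added to model 2
#
# The u update uses the one-time eigendecomposition K = V Lam V'. In
# eigencoordinates Ut = V'U the nm-dimensional conditional factorizes into n
# independent m-dimensional Gaussians with precision UE^-1 / lam_k + Sigma^-1.
# These n draws are vectorized by simultaneously diagonalizing UE against
# Sigma: with s = sqrt(Sigma), A = UE / (s s') = Q D Q', the conditional mean
# and covariance share the diagonal factor lam_k d_j / (1 + lam_k d_j), so the
# whole update is a handful of n x m matrix products per sweep.

.make_u_trans <- function(UE, Sigma) {
  s <- sqrt(Sigma)
  A <- UE / tcrossprod(s)
  eA <- eigen(.symmetrize(A), symmetric = TRUE)
  list(d = pmax(eA$values, 1e-12),
       M1 = eA$vectors / s,        # Sigma^-1/2 Q
       M2 = t(eA$vectors * s))     # Q' Sigma^1/2
}

.make_f_trans <- function(FE, Sigma) {
  P <- chol2inv(.chol_jitter(FE, "FE")) + diag(1 / Sigma, length(Sigma))
  Pinv <- .symmetrize(chol2inv(chol(P)))
  list(MF = Pinv / Sigma,          # Sigma^-1 Pinv (row j divided by Sigma_j)
       RF = chol(Pinv))
}

.multi_sweep <- function(st, dat, pr, ctl) {
  n <- dat$n; m <- dat$m
  if (is.null(ctl$fix$UE)) {
    Su <- pr$S0 + crossprod(st$Ut, st$Ut / dat$lam)
    st$UE <- .rinvwishart1(pr$df0 + n, .symmetrize(Su))
    st$trans <- NULL
  }
  if (dat$include_f && is.null(ctl$fix$FE)) {
    st$FE <- .rinvwishart1(pr$df0 + n, .symmetrize(pr$S0 + crossprod(st$F)))
    st$ftrans <- NULL
  }
  if (is.null(ctl$fix$Sigma)) {
    Rm <- st$Y - rep(st$mu, each = n) - st$U - st$F
    for (j in seq_len(m)) {
      sse <- sum(Rm[dat$obs[, j], j]^2)
      sc <- pr$S_eps[j] + sse
      if (isTRUE(ctl$corrupt)) sc <- sc * 1.3
      st$Sigma[j] <- sc / stats::rchisq(1, pr$df_eps[j] + dat$n_obs[j])
    }
    st$trans <- NULL; st$ftrans <- NULL
  }
  miss <- !dat$obs
  if (any(miss)) {
    Mn <- rep(st$mu, each = n) + st$U + st$F
    sd_cell <- rep(sqrt(st$Sigma), each = n)
    st$Y[miss] <- Mn[miss] + stats::rnorm(sum(miss)) * sd_cell[miss]
  }
  cm <- colSums(st$Y - st$U - st$F)
  prec_mu <- n / st$Sigma + (if (is.finite(dat$mu_prior_var)) 1 / dat$mu_prior_var else 0)
  st$mu <- cm / st$Sigma / prec_mu + stats::rnorm(m) / sqrt(prec_mu)

  if (is.null(st$trans)) st$trans <- .make_u_trans(st$UE, st$Sigma)
  tr <- st$trans
  Rt <- crossprod(dat$V, st$Y - rep(st$mu, each = n) - st$F)
  T1 <- Rt %*% tr$M1
  Cf <- outer(dat$lam, tr$d)
  Cf <- Cf / (1 + Cf)
  st$Ut <- (T1 * Cf + matrix(stats::rnorm(n * m), n, m) * sqrt(Cf)) %*% tr$M2
  st$U <- dat$V %*% st$Ut

  if (dat$include_f) {
    if (is.null(st$ftrans)) st$ftrans <- .make_f_trans(st$FE, st$Sigma)
    ft <- st$ftrans
    Rf <- st$Y - rep(st$mu, each = n) - st$U
    st$F <- Rf %*% ft$MF + matrix(stats::rnorm(n * m), n, m) %*% ft$RF
  }
  st
}

#' Fit the multi-environment Kronecker kernel model
#'
#' Gibbs sampler for the genotype-by-environment models with genetic effects
#' u ~ N(0, UE (x) K) (between-environment genetic covariance UE, kernel K),
#' optionally an extra non-marker genetic effect f ~ N(0, FE (x) I), diagonal
#' residual covariance Sigma (x) I, flat priors on the per-environment
#' intercepts, inverse-Wishart priors on UE and FE, and scaled inverse
#' chi-squared priors on the residual variances. All environments must share
#' the same line set; unobserved cells are handled by data augmentation and
#' predicted by the posterior mean of mu + u (+ f).
#'
#' @param pheno a \code{phenotype_table} with m >= 2 environments; every line
#'   must be observed in at least one environment.
#' @param K a \code{kernel_matrix} covering all lines.
#' @param include_f include the extra effect f with covariance FE (x) I
#'   (model with u and f); \code{FALSE} fits the u-only model.
#' @param prior a \code{prior_spec}; default \code{\link{default_multi_prior}}.
#' @param mcmc an \code{\link{mcmc_config}}.
#' @param fix optional list with any of \code{UE}, \code{FE}, \code{Sigma};
#'   a supplied value disables that update (oracle validation).
#' @param mu_prior_var Gaussian intercept-prior variance; \code{Inf} = flat.
#' @return a \code{posterior_chain} with retained draws of the intercepts,
#'   residual variances and the upper triangles of UE (and FE), posterior
#'   means of u (and f), the predicted grid, imputation means, and effective
#'   sample sizes.
#' @export
fit_multi <- function(pheno, K, include_f = TRUE, prior = NULL,
                      mcmc = mcmc_config(), fix = NULL, mu_prior_var = Inf) {
  stopifnot(inherits(pheno, "phenotype_table"), inherits(mcmc, "mcmc_config"))
  n <- nrow(pheno$values); m <- ncol(pheno$values)
  if (m < 2) stop("fit_multi requires at least 2 environments")
  n_obs <- colSums(pheno$observed)
  if (any(n_obs == 0))
    stop("environment with zero observed cells: ",
         paste(pheno$env_ids[n_obs == 0], collapse = ", "))
  if (any(rowSums(pheno$observed) == 0))
    stop("line observed in no environment: ",
         paste(pheno$line_ids[rowSums(pheno$observed) == 0][1:3], collapse = ", "))
  if (any(!is.finite(pheno$values[pheno$observed]))) stop("non-finite phenotype values")

  Kv <- if (inherits(K, "kernel_matrix")) K$values else as.matrix(K)
  kl <- if (inherits(K, "kernel_matrix")) K$line_ids else rownames(Kv)
  if (!is.null(kl)) {
    idx <- match(pheno$line_ids, kl)
    if (anyNA(idx)) stop("kernel does not cover all phenotyped lines")
    Kv <- Kv[idx, idx, drop = FALSE]
  } else if (nrow(Kv) != n) stop("kernel order must match line count")

  if (is.null(prior)) prior <- default_multi_prior(m)
  if (is.null(prior$S0)) stop("prior lacks the inverse-Wishart component (S0, df0)")
  if (length(prior$S_eps) == 1) prior$S_eps <- rep(prior$S_eps, m)
  if (length(prior$df_eps) == 1) prior$df_eps <- rep(prior$df_eps, m)

  e <- .eigen_kernel(Kv)
  dat <- list(V = e$vectors, lam = e$values, obs = pheno$observed, n = n, m = m,
              n_obs = n_obs, mu_prior_var = mu_prior_var, include_f = include_f)
  ctl <- list(fix = fix, corrupt = FALSE)

  mu0 <- vapply(seq_len(m), function(j) mean(pheno$values[pheno$observed[, j], j]), 0)
  v0 <- vapply(seq_len(m), function(j) {
    y <- pheno$values[pheno$observed[, j], j]
    if (length(y) > 1) stats::var(y) else 1
  }, 0)
  Y0 <- pheno$values
  for (j in seq_len(m)) Y0[!pheno$observed[, j], j] <- mu0[j]
  st <- list(mu = mu0,
             Ut = matrix(0, n, m), U = matrix(0, n, m), F = matrix(0, n, m),
             UE = if (!is.null(fix$UE)) as.matrix(fix$UE) else diag(pmax(v0 / 2, 1e-3), m),
             FE = if (!is.null(fix$FE)) as.matrix(fix$FE) else diag(pmax(v0 / 4, 1e-3), m),
             Sigma = if (!is.null(fix$Sigma)) as.numeric(fix$Sigma) else pmax(v0 / 2, 1e-3),
             Y = Y0, trans = NULL, ftrans = NULL)

  ut_idx <- which(upper.tri(diag(m), diag = TRUE))
  ut_names <- outer(seq_len(m), seq_len(m), function(i, j) paste0(i, "_", j))[ut_idx]
  cn <- c(paste0("mu_", pheno$env_ids), paste0("sigma2_", pheno$env_ids),
          paste0("UE_", ut_names), if (include_f) paste0("FE_", ut_names))
  R <- mcmc$n_retained
  draws <- matrix(NA_real_, R, length(cn), dimnames = list(NULL, cn))
  U_mean <- matrix(0, n, m); F_mean <- matrix(0, n, m)
  yhat_mean <- matrix(0, n, m); ymiss_mean <- matrix(0, n, m)
  UE_mean <- matrix(0, m, m); FE_mean <- matrix(0, m, m)
  u_draws <- if (mcmc$store_effects) matrix(NA_real_, R, n * m) else NULL

  n_kept <- mcmc$iterations - mcmc$burn_in  # running means use every post-burn-in sweep
  .with_seed(mcmc$seed, {
    r <- 0L
    for (it in seq_len(mcmc$iterations)) {
      st <- .multi_sweep(st, dat, prior, ctl)
      if (it > mcmc$burn_in) {
        U_mean <- U_mean + st$U
        F_mean <- F_mean + st$F
        yhat_mean <- yhat_mean + rep(st$mu, each = n) + st$U + st$F
        ymiss_mean <- ymiss_mean + st$Y
        UE_mean <- UE_mean + st$UE
        if (include_f) FE_mean <- FE_mean + st$FE
        if ((it - mcmc$burn_in) %% mcmc$thin == 0L && r < R) {
          r <- r + 1L
          draws[r, ] <- c(st$mu, st$Sigma, st$UE[ut_idx],
                          if (include_f) st$FE[ut_idx])
          if (!is.null(u_draws)) u_draws[r, ] <- as.numeric(st$U)
        }
      }
    }
  })
  dn <- list(pheno$line_ids, pheno$env_ids)
  en <- list(pheno$env_ids, pheno$env_ids)
  structure(list(
    model = if (include_f) "multi3" else "multi2",
    draws = draws, n_retained = R,
    mu_mean = colMeans(draws[, seq_len(m), drop = FALSE]),
    Sigma_mean = colMeans(draws[, m + seq_len(m), drop = FALSE]),
    UE_mean = structure(UE_mean / n_kept, dimnames = en),
    FE_mean = if (include_f) structure(FE_mean / n_kept, dimnames = en) else NULL,
    u_mean = structure(U_mean / n_kept, dimnames = dn),
    f_mean = if (include_f) structure(F_mean / n_kept, dimnames = dn) else NULL,
    yhat = structure(yhat_mean / n_kept, dimnames = dn),
    imputed = list(mask = !pheno$observed,
                   mean = ifelse(pheno$observed, NA_real_, ymiss_mean / n_kept)),
    u_draws = u_draws,
    ess = apply(draws, 2, .ess),
    prior = prior, mcmc = mcmc,
    line_ids = pheno$line_ids, env_ids = pheno$env_ids), class = "posterior_chain")
}

#' Posterior-mean between-environment correlation matrix
#'
#' Converts the posterior mean of UE (or FE) to a correlation matrix.
#'
#' @param chain a multi-environment \code{posterior_chain}.
#' @param which \code{"UE"} (default) or \code{"FE"}.
#' @return an m x m correlation matrix.
#' @export
env_correlations <- function(chain, which = c("UE", "FE")) {
  which <- match.arg(which)
  M <- if (which == "UE") chain$UE_mean else chain$FE_mean
  if (is.null(M)) stop("chain has no ", which, " component")
  stats::cov2cor(M)
}
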