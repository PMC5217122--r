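# Single-environment kernel regression: y = 1 mu + u + e, u ~ N(0, su2 K),
# e ~ N(0, se2 I). The u update works in the eigenbasis of K (one-time
# decomposition), where the conditional factorizes over eigencomponents.

# One Gibbs sweep. Update order keeps the scheme exact in the presence of
# missing cells: the error variance is drawn from its conditional given the
# observed cells only (missing cells marginalized), and the missing cells are
# redrawn immediately afterwards -- a joint (se2, y_miss) block.
.single_sweep <- function(st, dat, pr, ctl) {
  n <- dat$n
  if (is.null(ctl$fix_u2)) {
    sc <- pr$S_u + sum(st$ustar^2 / dat$lam)
    st$sig_u2 <- sc / stats::rchisq(1, pr$df_u + n)
  }
  if (is.null(ctl$fix_e2)) {
    r <- dat$y_obs - st$mu - st$u[dat$obs]
    sc <- pr$S_eps + sum(r^2)
    if (isTRUE(ctl$corrupt)) sc <- sc * 1.3
    st$sig_e2 <- sc / stats::rchisq(1, pr$df_eps + dat$n_obs)
  }
  miss <- !dat$obs
  if (any(miss))
    st$y[miss] <- st$mu + st$u[miss] + stats::rnorm(sum(miss)) * sqrt(st$sig_e2)
  prec_mu <- n / st$sig_e2 + (if (is.finite(dat$mu_prior_var)) 1 / dat$mu_prior_var else 0)
  st$mu <- sum(st$y - st$u) / st$sig_e2 / prec_mu + stats::rnorm(1) / sqrt(prec_mu)
  yt <- crossprod(dat$V, st$y - st$mu)
  prec <- 1 / (st$sig_u2 * dat$lam) + 1 / st$sig_e2
  st$ustar <- as.numeric(yt / st$sig_e2 / prec + stats::rnorm(n) / sqrt(prec))
  st$u <- as.numeric(dat$V %*% st$ustar)
  st
}

#' Fit the single-environment kernel regression
#'
#' Gibbs sampler for y = 1 mu + u + e with u ~ N(0, su2 K), e ~ N(0, se2 I),
#' a flat prior on the intercept and scaled inverse chi-squared priors on both
#' variances. Unobserved cells are handled by data augmentation; predictions
#' are posterior means of mu + u (lower Monte Carlo variance than the
#' augmented responses).
#'
#' @param pheno a one-environment \code{phenotype_table}; unobserved cells are
#'   predicted.
#' @param K a \code{kernel_matrix} covering all lines of \code{pheno}.
#' @param prior a \code{prior_spec}; default \code{\link{default_single_prior}}.
#' @param mcmc an \code{\link{mcmc_config}}.
#' @param fix_variances optional list with elements \code{sigma_u2} and/or
#'   \code{sigma_e2}; a supplied value disables that variance update (used for
#'   conjugate-oracle validation).
#' @param mu_prior_var variance of a Gaussian prior on the intercept;
#'   \code{Inf} (default) gives the flat prior.
#' @return a \code{posterior_chain} with retained draws of (mu, sigma_u2,
#'   sigma_e2), posterior means of u and of the predicted grid, imputation
#'   means for unobserved cells, and effective sample sizes.
#' @export
fit_single <- function(pheno, K, prior = NULL, mcmc = mcmc_config(),
                       fix_variances = NULL, mu_prior_var = Inf) {
  stopifnot(inherits(pheno, "phenotype_table"), inherits(mcmc, "mcmc_config"))
  if (ncol(pheno$values) != 1) stop("fit_single expects exactly one environment")
  Kv <- if (inherits(K, "kernel_matrix")) K$values else as.matrix(K)
  kl <- if (inherits(K, "kernel_matrix")) K$line_ids else rownames(Kv)
  if (!is.null(kl)) {
    idx <- match(pheno$line_ids, kl)
    if (anyNA(idx)) stop("kernel does not cover lines: ",
                         paste(pheno$line_ids[is.na(idx)][1:min(3, sum(is.na(idx)))], collapse = ", "))
    Kv <- Kv[idx, idx, drop = FALSE]
  } else if (nrow(Kv) != nrow(pheno$values)) stop("kernel order must match line count")
  obs <- pheno$observed[, 1]
  y_obs <- pheno$values[obs, 1]
  if (sum(obs) < 2) stop("need at least 2 observed values")
  if (any(!is.finite(y_obs))) stop("non-finite phenotype values")
  if (is.null(prior)) prior <- default_single_prior(y_obs, Kv)

  n <- nrow(Kv)
  e <- .eigen_kernel(Kv)
  dat <- list(V = e$vectors, lam = e$values, obs = obs, y_obs = y_obs,
              n = n, n_obs = sum(obs), mu_prior_var = mu_prior_var)
  ctl <- list(fix_u2 = fix_variances$sigma_u2, fix_e2 = fix_variances$sigma_e2,
              corrupt = FALSE)

  st <- list(mu = mean(y_obs), u = numeric(n), ustar = numeric(n),
             sig_u2 = if (!is.null(ctl$fix_u2)) ctl$fix_u2 else prior$S_u / (prior$df_u + 2),
             sig_e2 = if (!is.null(ctl$fix_e2)) ctl$fix_e2 else prior$S_eps / (prior$df_eps + 2),
             y = ifelse(obs, pheno$values[, 1], mean(y_obs)))

  R <- mcmc$n_retained
  draws <- matrix(NA_real_, R, 3, dimnames = list(NULL, c("mu", "sigma_u2", "sigma_e2")))
  u_draws <- if (mcmc$store_effects) matrix(NA_real_, R, n) else NULL
  u_mean <- numeric(n); yhat_mean <- numeric(n); ymiss_mean <- numeric(n)
  n_kept <- mcmc$iterations - mcmc$burn_in  # running means use every post-burn-in sweep
  .with_seed(mcmc$seed, {
    r <- 0L
    for (it in seq_len(mcmc$iterations)) {
      st <- .single_sweep(st, dat, prior, ctl)
      if (it > mcmc$burn_in) {
        u_mean <- u_mean + st$u
        yhat_mean <- yhat_mean + st$mu + st$u
        ymiss_mean <- ymiss_mean + st$y
        if ((it - mcmc$burn_in) %% mcmc$thin == 0L && r < R) {
          r <- r + 1L
          draws[r, ] <- c(st$mu, st$sig_u2, st$sig_e2)
          if (!is.null(u_draws)) u_draws[r, ] <- st$u
        }
      }
    }
  })
  u_mean <- u_mean / n_kept; yhat_mean <- yhat_mean / n_kept
  ymiss_mean <- ymiss_mean / n_kept
  yhat <- matrix(yhat_mean, ncol = 1, dimnames = list(pheno$line_ids, pheno$env_ids))
  structure(list(
    model = "single", draws = draws, n_retained = R,
    mu_mean = mean(draws[, "mu"]),
    sigma_u2_mean = mean(draws[, "sigma_u2"]), sigma_e2_mean = mean(draws[, "sigma_e2"]),
    u_mean = matrix(u_mean, ncol = 1, dimnames = list(pheno$line_ids, pheno$env_ids)),
    yhat = yhat,
    imputed = list(mask = !pheno$observed,
                   mean = ifelse(pheno$observed, NA_real_, ymiss_mean)),
    u_draws = u_draws,
    ess = apply(draws, 2, .ess),
    prior = prior, mcmc = mcmc,
    line_ids = pheno$line_ids, env_ids = pheno$env_ids), class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf("posterior_chain (%s): %d retained draws, %d lines x %d environments\n",
              x$model, x$n_retained, length(x$line_ids), length(x$env_ids)))
  if (x$model == "single") {
    cat(sprintf("  sigma_u2 = %.4f, sigma_e2 = %.4f\n",
                x$sigma_u2_mean, x$sigma_e2_mean))
  } else {
    cat("  posterior mean UE:\n")
    print(round(x$UE_mean, 4))
    if (!is.null(x$FE_mean)) { cat("  posterior mean FE:\n"); print(round(x$FE_mean, 4)) }
    cat("  posterior mean residual variances:",
        paste(round(x$Sigma_mean, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predicted phenotype grid
#'
#' @param object a \code{posterior_chain}.
#' @param ... unused.
#' @return the n x m posterior-mean predicted grid (mu + u (+ f)).
#' @export
predict.posterior_chain <- function(object, ...) object$yhat
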