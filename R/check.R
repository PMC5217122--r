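# "Getting it right" harness: alternate (data | parameters) simulation with one
# Gibbs sweep (parameters | data), using exactly the sweep code of fit_single /
# fit_multi. The stationary distribution of the parameter draws must be the
# prior, so their moments are compared against direct prior draws.

.scc_prior_default <- function(model, m) {
  # Moment-friendly harness prior: the paper-default df0 = m has an undefined
  # inverse-Wishart mean, which would make a mean-based check ill-posed. The
  # samplers themselves never assume df0 > m + 1.
  if (model == "single") prior_spec(df_eps = 6, S_eps = 2, df_u = 6, S_u = 2)
  else prior_spec(df_eps = rep(6, m), S_eps = rep(2, m), S0 = diag(m), df0 = m + 4)
}

#' Successive-conditional sampler check
#'
#' Runs the successive-conditional ("getting it right") simulator for the
#' requested model at small dimensions: parameters start at a prior draw, then
#' each cycle simulates a complete data set from the model and applies one
#' Gibbs sweep of the fitting code. The marginal distribution of the parameter
#' draws must equal the prior; the report compares the mean of every tracked
#' variance/covariance parameter (and the intercepts, which are given a proper
#' N(0, 1) prior inside the harness so that they can be prior-sampled) with
#' direct prior draws, flagging any discrepancy larger than
#' \code{z_threshold} combined standard errors (Gibbs-side SEs are
#' autocorrelation-adjusted via effective sample size).
#'
#' @param model \code{"single"}, \code{"multi2"} (u only) or \code{"multi3"}
#'   (u and f).
#' @param n,m numbers of lines and environments (keep small, e.g. n = 10).
#' @param cycles number of successive-conditional cycles.
#' @param prior optional \code{prior_spec}; the default uses moment-friendly
#'   hyperparameters (df0 = m + 4, scaled-inv-chi2 df = 6, S = 2).
#' @param seed RNG seed (also fixes the kernel used).
#' @param corrupt deliberately corrupt the residual-variance conditional
#'   (sensitivity fixture; the check must then fail).
#' @param n_prior_draws Monte Carlo size for the direct prior draws.
#' @param z_threshold flag threshold in combined SEs (default 4).
#' @return an object of class \code{scc_report}: a data frame of per-parameter
#'   comparisons with attributes \code{pass} (logical) and \code{model}.
#' @export
successive_conditional_check <- function(model = c("single", "multi2", "multi3"),
                                         n = 10, m = 2, cycles = 20000,
                                         prior = NULL, seed = 1L,
                                         corrupt = FALSE,
                                         n_prior_draws = 100000,
                                         z_threshold = 4) {
  model <- match.arg(model)
  n <- .stopifnot_count(n, "n"); m <- .stopifnot_count(m, "m")
  if (is.null(prior)) prior <- .scc_prior_default(model, m)
  include_f <- model == "multi3"

  out <- .with_seed(seed, {
    # fixed, well-conditioned kernel with unit mean diagonal
    Z <- matrix(stats::rnorm(n * max(2 * n, 20)), n)
    Zs <- sweep(Z, 2, colMeans(Z))
    Zs <- sweep(Zs, 2, sqrt(colMeans(Zs^2)), "/")
    Kv <- tcrossprod(Zs) / ncol(Zs)
    e <- .eigen_kernel(Kv)

    if (model == "single") {
      dat <- list(V = e$vectors, lam = e$values, obs = rep(TRUE, n), y_obs = NULL,
                  n = n, n_obs = n, mu_prior_var = 1)
      ctl <- list(fix_u2 = NULL, fix_e2 = NULL, corrupt = corrupt)
      st <- list(mu = stats::rnorm(1),
                 sig_u2 = rinvchisq(1, prior$df_u, prior$S_u),
                 sig_e2 = rinvchisq(1, prior$df_eps, prior$S_eps),
                 ustar = NULL, u = NULL, y = NULL)
      st$ustar <- stats::rnorm(n) * sqrt(st$sig_u2 * dat$lam)
      st$u <- as.numeric(e$vectors %*% st$ustar)
      tracked <- matrix(NA_real_, cycles, 3,
                        dimnames = list(NULL, c("mu", "sigma_u2", "sigma_e2")))
      for (cy in seq_len(cycles)) {
        st$y <- st$mu + st$u + stats::rnorm(n) * sqrt(st$sig_e2)
        dat$y_obs <- st$y
        st <- .single_sweep(st, dat, prior, ctl)
        tracked[cy, ] <- c(st$mu, st$sig_u2, st$sig_e2)
      }
      prior_mc <- cbind(mu = stats::rnorm(n_prior_draws),
                        sigma_u2 = rinvchisq(n_prior_draws, prior$df_u, prior$S_u),
                        sigma_e2 = rinvchisq(n_prior_draws, prior$df_eps, prior$S_eps))
    } else {
      dat <- list(V = e$vectors, lam = e$values, obs = matrix(TRUE, n, m),
                  n = n, m = m, n_obs = rep(n, m), mu_prior_var = 1,
                  include_f = include_f)
      ctl <- list(fix = NULL, corrupt = corrupt)
      ch_ue <- function(M) chol(M)
      UE0 <- .rinvwishart1(prior$df0, prior$S0)
      FE0 <- .rinvwishart1(prior$df0, prior$S0)
      st <- list(mu = stats::rnorm(m),
                 UE = UE0, FE = FE0,
                 Sigma = rinvchisq(m, prior$df_eps[1], prior$S_eps[1]),
                 Ut = (sqrt(e$values) * matrix(stats::rnorm(n * m), n, m)) %*% ch_ue(UE0),
                 F = if (include_f) matrix(stats::rnorm(n * m), n, m) %*% ch_ue(FE0)
                     else matrix(0, n, m),
                 Y = NULL, trans = NULL, ftrans = NULL)
      st$U <- e$vectors %*% st$Ut
      ut_idx <- which(upper.tri(diag(m), diag = TRUE))
      ut_names <- outer(seq_len(m), seq_len(m), function(i, j) paste0(i, "_", j))[ut_idx]
      cn <- c(paste0("mu_", seq_len(m)), paste0("sigma2_", seq_len(m)),
              paste0("UE_", ut_names), if (include_f) paste0("FE_", ut_names))
      tracked <- matrix(NA_real_, cycles, length(cn), dimnames = list(NULL, cn))
      for (cy in seq_len(cycles)) {
        st$Y <- rep(st$mu, each = n) + st$U + st$F +
          matrix(stats::rnorm(n * m), n, m) * rep(sqrt(st$Sigma), each = n)
        st <- .multi_sweep(st, dat, prior, ctl)
        tracked[cy, ] <- c(st$mu, st$Sigma, st$UE[ut_idx],
                           if (include_f) st$FE[ut_idx])
      }
      np_iw <- min(n_prior_draws, 20000L)
      iw_flat <- function() {
        t(apply(rinvwishart(np_iw, prior$df0, prior$S0), 3, function(W) W[ut_idx]))
      }
      prior_mc <- cbind(matrix(stats::rnorm(np_iw * m), ncol = m),
                        matrix(rinvchisq(np_iw * m, prior$df_eps[1],
                                         prior$S_eps[1]), ncol = m),
                        iw_flat(),
                        if (include_f) iw_flat())
      colnames(prior_mc) <- cn
    }
    list(tracked = tracked, prior_mc = prior_mc)
  })

  tracked <- out$tracked; prior_mc <- out$prior_mc
  res <- data.frame(parameter = colnames(tracked),
                    gibbs_mean = colMeans(tracked),
                    prior_mean = colMeans(prior_mc),
                    row.names = NULL, stringsAsFactors = FALSE)
  se_g <- vapply(seq_len(ncol(tracked)), function(k) {
    stats::sd(tracked[, k]) / sqrt(.ess(tracked[, k]))
  }, 0)
  se_p <- apply(prior_mc, 2, stats::sd) / sqrt(nrow(prior_mc))
  res$se <- sqrt(se_g^2 + se_p^2)
  res$z <- (res$gibbs_mean - res$prior_mean) / res$se
  res$flag <- abs(res$z) > z_threshold
  structure(res, class = c("scc_report", "data.frame"),
            pass = !any(res$flag), model = model)
}

#' @export
print.scc_report <- function(x, ...) {
  cat(sprintf("successive-conditional check (%s): %s\n", attr(x, "model"),
              if (attr(x, "pass")) "PASS" else "FAIL"))
  print.data.frame(cbind(x[, c("parameter", "gibbs_mean", "prior_mean")],
                         z = round(x$z, 2), flag = x$flag), row.names = FALSE)
  invisible(x)
}
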