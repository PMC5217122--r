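#' Prior specification
#'
#' Bundles the hyperparameters of the variance priors: scaled inverse
#' chi-squared priors on the residual (and, for single-environment fits, the
#' genetic) variances, and an inverse-Wishart prior (scale \code{S0}, degrees
#' of freedom \code{df0}) on the between-environment covariance matrices.
#'
#' The scaled inverse chi-squared convention used throughout the package is
#' density proportional to (s2)^-(df/2 + 1) exp(-S / (2 s2)), i.e. S / chisq(df),
#' with prior mode S / (df + 2) and prior mean S / (df - 2) for df > 2.
#'
#' @param df_eps,S_eps residual-variance prior degrees of freedom and scale
#'   (scalar or one per environment).
#' @param df_u,S_u genetic-variance prior (single-environment model).
#' @param S0 m x m positive-definite scale matrix (multi-environment models).
#' @param df0 inverse-Wishart degrees of freedom (>= m).
#' @return an object of class \code{prior_spec}.
#' @export
prior_spec <- function(df_eps, S_eps, df_u = NULL, S_u = NULL,
                       S0 = NULL, df0 = NULL) {
  if (any(df_eps <= 0) || any(S_eps <= 0)) stop("df_eps and S_eps must be > 0")
  if (!is.null(df_u) && (df_u <= 0 || S_u <= 0)) stop("df_u and S_u must be > 0")
  if (!is.null(S0)) {
    S0 <- as.matrix(S0)
    .check_pd(S0, "S0")
    if (is.null(df0) || df0 < nrow(S0)) stop("df0 must be >= m")
  }
  structure(list(df_eps = df_eps, S_eps = S_eps, df_u = df_u, S_u = S_u,
                 S0 = S0, df0 = df0), class = "prior_spec")
}

#' Default single-environment prior
#'
#' Applies the rule that the model explains 50\% of the phenotypic variance:
#' df_eps = df_u = 5, S_eps = 0.5 var(y) (df_eps + 2), and
#' S_u = 0.5 var(y) (df_u + 2) / mean(diag(K)), so that the prior mode of the
#' error variance is 0.5 var(y).
#'
#' @param y_env numeric vector of observed phenotypes for one environment, or
#'   a one-environment \code{phenotype_table}.
#' @param K the \code{kernel_matrix} used in the fit.
#' @return a \code{prior_spec}.
#' @export
default_single_prior <- function(y_env, K) {
  if (inherits(y_env, "phenotype_table")) {
    stopifnot(ncol(y_env$values) == 1)
    y_env <- y_env$values[y_env$observed[, 1], 1]
  }
  y_env <- as.numeric(y_env)
  if (length(y_env) < 2) stop("need at least 2 observed values")
  vy <- stats::var(y_env)
  if (vy == 0) stop("phenotype has zero variance")
  Kd <- if (inherits(K, "kernel_matrix")) mean(diag(K$values)) else mean(diag(as.matrix(K)))
  df <- 5
  prior_spec(df_eps = df, S_eps = 0.5 * vy * (df + 2),
             df_u = df, S_u = 0.5 * vy * (df + 2) / Kd)
}

#' Default multi-environment prior
#'
#' Inverse-Wishart scale matrix S0 = identity of order m with df0 = m for the
#' between-environment covariances, and a scaled inverse chi-squared prior
#' with degrees of freedom 1 and scale 1 for each per-environment residual
#' variance.
#'
#' @param m number of environments (>= 2).
#' @return a \code{prior_spec}.
#' @export
default_multi_prior <- function(m) {
  m <- .stopifnot_count(m, "m")
  if (m < 2) stop("multi-environment prior requires m >= 2 (use the single-environment model)")
  prior_spec(df_eps = 1, S_eps = 1, S0 = diag(m), df0 = m)
}

#' Scaled inverse chi-squared draws
#'
#' Samples from the distribution of S / chisq(df), density proportional to
#' (x)^-(df/2 + 1) exp(-S / (2x)); mean S / (df - 2) for df > 2, mode
#' S / (df + 2).
#'
#' @param n number of draws.
#' @param df degrees of freedom (> 0).
#' @param scale scale S (> 0).
#' @return numeric vector of positive draws.
#' @export
rinvchisq <- function(n, df, scale) {
  if (any(df <= 0) || any(scale <= 0)) stop("df and scale must be > 0")
  scale / stats::rchisq(n, df)
}

#' Inverse-Wishart draws
#'
#' Samples m x m positive-definite matrices with density proportional to
#' |W|^-((df0 + m + 1)/2) exp(-tr(S0 W^-1)/2); mean S0 / (df0 - m - 1) when
#' df0 > m + 1 (undefined otherwise, as with the default df0 = m prior).
#'
#' @param n number of draws.
#' @param df0 degrees of freedom (>= m).
#' @param S0 positive-definite scale matrix.
#' @return an m x m x n array of symmetric positive-definite draws.
#' @export
rinvwishart <- function(n, df0, S0) {
  S0 <- as.matrix(S0)
  m <- nrow(S0)
  .check_pd(S0, "S0")
  if (df0 < m) stop("df0 must be >= m")
  S0inv <- chol2inv(.chol_jitter(S0, "S0"))
  W <- stats::rWishart(n, df0, .symmetrize(S0inv))
  out <- array(NA_real_, dim = dim(W))
  for (i in seq_len(n)) out[, , i] <- .symmetrize(chol2inv(chol(W[, , i])))
  out
}

.rinvwishart1 <- function(df0, S0) {
  W <- stats::rWishart(1, df0, .symmetrize(chol2inv(.chol_jitter(S0))))[, , 1]
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch)) { # numerically singular Wishart draw: jitter once, then fail
    W <- W + diag(1e-8 * mean(diag(W)), nrow(W))
    ch <- chol(W)
  }
  .symmetrize(chol2inv(ch))
}

#' MCMC schedule
#'
#' @param iterations total Gibbs iterations (default 30000).
#' @param burn_in discarded initial iterations (default 5000).
#' @param thin thinning interval (default 5); the retained draw count is
#'   floor((iterations - burn_in) / thin).
#' @param seed integer RNG seed; identical seeds and inputs give bitwise
#'   identical chains.
#' @param store_effects store per-draw genetic-effect grids (memory heavy;
#'   default \code{FALSE}, running means are always kept).
#' @return an object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(iterations = 30000, burn_in = 5000, thin = 5,
                        seed = 1L, store_effects = FALSE) {
  iterations <- .stopifnot_count(iterations, "iterations")
  burn_in <- .stopifnot_count(burn_in, "burn_in")
  thin <- max(1L, .stopifnot_count(thin, "thin"))
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), store_effects = isTRUE(store_effects),
                 n_retained = as.integer((iterations - burn_in) %/% thin)),
            class = "mcmc_config")
}
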