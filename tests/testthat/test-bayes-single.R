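test_that("fixed-variance posterior mean of u matches the conjugate Gaussian oracle", {
  n <- 25
  X <- std_markers(n, 120, seed = 21)
  K <- linear_kernel(X)
  set.seed(22)
  y <- as.numeric(t(chol(K$values + diag(1e-6, n))) %*% rnorm(n)) + rnorm(n)
  tab <- phenotype_table(matrix(y, ncol = 1, dimnames = list(X$line_ids, "E1")))
  fit <- fit_single(tab, K, prior = prior_spec(5, 3.5, 5, 3.5),
                    mcmc = mcmc_config(15000, 3000, 3, seed = 23),
                    fix_variances = list(sigma_u2 = 1, sigma_e2 = 1))
  orc <- oracle_gblup_mean(y, K$values)
  expect_lt(max(abs(fit$u_mean[, 1] - orc$u)), 0.03)
  expect_lt(abs(fit$mu_mean - orc$mu), 0.02)
})

test_that("constant phenotypes attribute everything to the intercept", {
  n <- 30
  K <- linear_kernel(std_markers(n, 60, seed = 24))
  tab <- phenotype_table(matrix(2.5, n, 1, dimnames = list(K$line_ids, "E1")))
  # constant y has zero variance: supply an explicit prior
  fit <- fit_single(tab, K, prior = prior_spec(5, 0.35, 5, 0.35),
                    mcmc = mcmc_config(6000, 1000, 5, seed = 25))
  expect_lt(abs(fit$mu_mean - 2.5), 0.05)
  expect_lt(max(abs(fit$u_mean)), 0.05)
})

test_that("chains are bitwise reproducible and seeds matter", {
  n <- 20
  K <- linear_kernel(std_markers(n, 50, seed = 26))
  set.seed(27)
  tab <- phenotype_table(matrix(rnorm(n), ncol = 1,
                                dimnames = list(K$line_ids, "E1")))
  f1 <- fit_single(tab, K, mcmc = mcmc_config(2000, 500, 5, seed = 7))
  f2 <- fit_single(tab, K, mcmc = mcmc_config(2000, 500, 5, seed = 7))
  f3 <- fit_single(tab, K, mcmc = mcmc_config(2000, 500, 5, seed = 8))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$u_mean, f2$u_mean)
  expect_false(identical(f1$draws, f3$draws))
  # fitting must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99)
  invisible(fit_single(tab, K, mcmc = mcmc_config(500, 100, 2, seed = 1)))
  expect_identical(rnorm(3), before)
})

test_that("values at unobserved cells are ignored and imputed by augmentation", {
  n <- 30
  K <- linear_kernel(std_markers(n, 60, seed = 28))
  set.seed(29)
  y <- rnorm(n)
  obs <- rep(TRUE, n); obs[c(3, 11, 19)] <- FALSE
  mk <- function(vals) phenotype_table(matrix(vals, ncol = 1, dimnames = list(K$line_ids, "E1")),
                                       observed = matrix(obs, ncol = 1))
  cfg <- mcmc_config(2000, 500, 5, seed = 30)
  fa <- fit_single(mk(y), K, mcmc = cfg)
  y2 <- y; y2[!obs] <- 1e6                     # garbage at unobserved cells
  fb <- fit_single(mk(y2), K, mcmc = cfg)
  expect_identical(fa$draws, fb$draws)         # likelihood never touches them
  expect_true(all(is.finite(fa$imputed$mean[!obs, 1])))
  expect_true(all(is.na(fa$imputed$mean[obs, 1])))
})

test_that("input validation errors are explicit", {
  n <- 12
  K <- linear_kernel(std_markers(n, 30, seed = 31))
  y <- rnorm(n); y[2] <- Inf
  tab <- phenotype_table(matrix(y, ncol = 1, dimnames = list(K$line_ids, "E1")))
  expect_error(fit_single(tab, K, mcmc = mcmc_config(100, 10, 1)), "non-finite")
  two_env <- phenotype_table(matrix(rnorm(2 * n), n, 2, dimnames = list(K$line_ids, NULL)))
  expect_error(fit_single(two_env, K), "one environment")
  small <- phenotype_table(matrix(c(1, rep(NA, n - 1)), ncol = 1,
                                  dimnames = list(K$line_ids, "E1")))
  expect_error(fit_single(small, K), "at least 2")
})
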