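test_that("simulated markers follow the requested allele-frequency regime", {
  X <- simulate_markers(1000, 50, maf_range = c(0.5, 0.5), seed = 2)
  # expected dosage mean 2 * 0.5 = 1; SE of the overall mean is tiny
  expect_lt(abs(mean(X$values) - 1), 3 * sqrt(0.5 / (1000 * 50)))

  X2 <- simulate_markers(400, 2000, maf_range = c(0.05, 0.5), seed = 3)
  surv <- standardize_markers(X2, maf_threshold = 0.05)
  expect_gte(ncol(surv$values) / 2000, 0.95)

  expect_identical(simulate_markers(50, 30, seed = 7)$values,
                   simulate_markers(50, 30, seed = 7)$values)
  expect_error(simulate_markers(1, 10), "n and p")
  expect_error(simulate_markers(10, 10, maf_range = c(0, 0.6)), "maf_range")
})

test_that("the generator reproduces its own covariance structure", {
  n <- 5000; m <- 2
  UE <- matrix(c(1, 0.8, 0.8, 1), 2)
  sc <- simulation_scenario(n = n, m = m, p = 10, UE_true = UE,
                            FE_true = diag(0.2, 2), Sigma_true = c(0.3, 0.5),
                            seed = 11)
  sim <- simulate_multienv_phenotypes(sc, K = diag(n))
  # u columns: sample covariance within +/- 0.05 of UE entrywise (K = I)
  Cu <- cov(sim$truth$U)
  expect_lt(max(abs(Cu - UE)), 0.05)
  # per-environment variance decomposition UE_jj * mean(diag K) + FE_jj + Sigma_jj
  vy <- apply(sim$table$values, 2, var)
  expected <- diag(UE) + 0.2 + c(0.3, 0.5)
  # 3 SE of a sample variance of a normal: var * sqrt(2/(n-1))
  expect_true(all(abs(vy - expected) < 3 * expected * sqrt(2 / (n - 1))))
})

test_that("the noise-free limit returns mu + u and outputs are reproducible", {
  n <- 60
  K <- linear_kernel(std_markers(n, 100, seed = 12))
  sc <- simulation_scenario(n = n, m = 3, p = 100,
                            UE_true = diag(0.7, 3), Sigma_true = rep(1e-6, 3),
                            mu_true = c(1, -1, 0), seed = 13)
  sim <- simulate_multienv_phenotypes(sc, K = K)
  expect_lt(max(abs(sim$table$values -
                      (rep(c(1, -1, 0), each = n) + sim$truth$U))), 1e-2)
  sim2 <- simulate_multienv_phenotypes(sc, K = K)
  expect_identical(sim$table$values, sim2$table$values)
})

test_that("the epistatic architecture needs markers and changes the genetic draw", {
  n <- 50
  X <- std_markers(n, 80, seed = 14)
  sc <- simulation_scenario(n = n, m = 2, p = 80, UE_true = diag(0.7, 2),
                            Sigma_true = rep(0.3, 2),
                            architecture = "epistatic", seed = 15)
  expect_error(simulate_multienv_phenotypes(sc), "marker_matrix")
  sim <- simulate_multienv_phenotypes(sc, X = X)
  expect_equal(dim(sim$truth$U), c(n, 2))
  # genetic columns standardized to the UE_true scale
  expect_equal(unname(apply(sim$truth$U, 2, sd)), rep(sqrt(0.7), 2), tolerance = 0.05)
})

test_that("scenario validation and presets work", {
  expect_error(simulation_scenario(UE_true = matrix(c(1, 2, 2, 1), 2), m = 2),
               "positive definite")
  expect_error(simulation_scenario(m = 3, Sigma_true = c(1, 1)), "Sigma_true")
  sc <- load_scenario("wheat1_like", n = 30, p = 50)
  expect_s3_class(sc, "simulation_scenario")
  expect_equal(sc$m, 4)
  expect_equal(sc$n, 30)                 # override applied
  expect_lt(max(eigen(sc$UE_true, TRUE, TRUE)$values), 2)
  expect_error(load_scenario("no_such_preset"), "unknown scenario")
})
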