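test_that("standardize_markers applies the MAF filter on observed calls and reports drops", {
  # 100 lines; marker M1 has minor-allele count 5 (freq 0.025), M2 is common
  g1 <- c(rep(1, 5), rep(0, 95))
  g2 <- rbinom(100, 2, 0.4)
  raw <- marker_matrix(cbind(M1 = g1, M2 = g2))
  out <- standardize_markers(raw, maf_threshold = 0.05)
  rep <- attr(out, "qc_report")
  expect_equal(rep$marker_id, "M1")
  expect_equal(rep$reason, "maf_below_threshold")
  expect_equal(out$marker_ids, "M2")

  # constant column dropped as zero variance regardless of threshold
  raw2 <- marker_matrix(cbind(A = rep(2, 10), B = c(rep(0, 5), rep(2, 5))))
  out2 <- standardize_markers(raw2, maf_threshold = 0)
  expect_equal(attr(out2, "qc_report")$reason, "zero_variance")
  expect_equal(out2$marker_ids, "B")
})

test_that("standardization centers and scales by the population SD", {
  raw <- marker_matrix(cbind(M = c(0, 1, 2, 1), F = c(0, 2, 0, 2)))
  out <- standardize_markers(raw, maf_threshold = 0)
  # hand oracle: mean 1, population SD sqrt(1/2)
  expect_equal(out$values[, "M"], c(-1, 0, 1, 0) / sqrt(0.5),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(out$is_standardized)
})

test_that("imputation modes fill missing calls and errors are explicit", {
  g <- cbind(M1 = c(0, 1, 2, NA, 1, 0), M2 = c(2, 2, 0, 0, NA, 2))
  raw <- marker_matrix(g)
  mean_imp <- standardize_markers(raw, maf_threshold = 0, impute_mode = "mean")
  expect_false(anyNA(mean_imp$values))
  draw1 <- standardize_markers(raw, maf_threshold = 0, impute_mode = "bernoulli_draw", seed = 9)
  draw2 <- standardize_markers(raw, maf_threshold = 0, impute_mode = "bernoulli_draw", seed = 9)
  expect_identical(draw1$values, draw2$values)

  expect_error(standardize_markers(marker_matrix(cbind(M = rep(1, 4)))),
               "no markers survive QC")
  allmiss <- marker_matrix(rbind(c(0, 1), c(NA, NA)), line_ids = c("L1", "Lbad"))
  expect_error(standardize_markers(allmiss), "Lbad")
  expect_error(standardize_markers(mean_imp), "already standardized")
  expect_error(standardize_markers(raw, maf_threshold = 0.5), "maf_threshold")
})

test_that("linear kernel matches hand and brute-force oracles and validates input", {
  X <- marker_matrix(rbind(c(1, -1), c(-1, 1)), is_standardized = TRUE)
  K <- linear_kernel(X)
  expect_equal(K$values, rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)
  expect_identical(K$values, t(K$values))

  Xr <- std_markers(5, 50, seed = 2)
  Kr <- linear_kernel(Xr)
  expect_equal(Kr$values, oracle_linear_kernel(Xr$values),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(linear_kernel(marker_matrix(matrix(0:1, 2, 2))), "standardized")
})

test_that("standardize -> linear kernel is invariant to marker column order", {
  raw <- simulate_markers(20, 40, seed = 3)
  perm <- sample(40)
  raw_p <- marker_matrix(raw$values[, perm], raw$line_ids, raw$marker_ids[perm])
  K1 <- linear_kernel(standardize_markers(raw, maf_threshold = 0))
  K2 <- linear_kernel(standardize_markers(raw_p, maf_threshold = 0))
  expect_equal(K1$values, K2$values, tolerance = 1e-12)
})

test_that("squared distances: hand values, zero diagonal, median scaling", {
  X <- marker_matrix(rbind(c(1, -1), c(-1, 1)), is_standardized = TRUE)
  D2 <- squared_distances(X, scale = "none")
  expect_equal(D2[1, 2], 8)           # (1 - (-1))^2 + (-1 - 1)^2
  expect_equal(diag(D2), rep(0, 2), ignore_attr = TRUE)

  # duplicate a line before standardization: identical rows -> zero distance
  raw <- simulate_markers(12, 30, seed = 4)
  vals <- raw$values
  vals[2, ] <- vals[1, ]
  dup <- standardize_markers(marker_matrix(vals), maf_threshold = 0)
  Dm <- squared_distances(dup, scale = "median")
  expect_equal(Dm[1, 2], 0)
  expect_equal(median(Dm[upper.tri(Dm)]), 1)   # scaling by the off-diagonal median
  expect_equal(attr(Dm, "scale_method"), "median")

  X1 <- marker_matrix(matrix(rnorm(6), 1), is_standardized = FALSE)
  X1$is_standardized <- TRUE
  expect_error(squared_distances(X1, scale = "median"), "2 lines")
})

test_that("gaussian kernel: closed forms, monotonicity, limits, PD", {
  X <- std_markers(15, 40, seed = 5)
  D2 <- squared_distances(X)
  K <- gaussian_kernel(D2, 0.8)
  expect_equal(diag(K$values), rep(1, 15), ignore_attr = TRUE)
  expect_true(all(K$values > 0 & K$values <= 1))

  D <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(gaussian_kernel(D, 0.5)$values[1, 2], exp(-1), tolerance = 1e-12)
  # strictly decreasing in h off the diagonal
  ks <- sapply(c(0.1, 0.5, 1, 2, 5), function(h) gaussian_kernel(D2, h)$values[1, 2])
  expect_true(all(diff(ks) < 0))
  # h -> 0+ limit: all-ones
  expect_lt(max(abs(gaussian_kernel(D2, 1e-12)$values - 1)), 1e-8)
  # PD for distinct rows
  ev <- eigen(K$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(gaussian_kernel(D2, 0), "h must be > 0")
  expect_error(gaussian_kernel(D2, -1), "h must be > 0")
})

test_that("kernel invariants hold across random inputs (property)", {
  for (seed in 1:5) {
    X <- std_markers(10 + seed, 25, seed = seed)
    K1 <- linear_kernel(X)                      # constructor validates symmetry/PSD
    K2 <- gaussian_kernel(squared_distances(X), h = 0.5 + seed / 4)
    expect_s3_class(K1, "kernel_matrix")
    expect_s3_class(K2, "kernel_matrix")
    expect_equal(mean(diag(K1$values)), 1, tolerance = 0.3)
  }
})

test_that("bandwidth estimation recovers the generating h and handles degenerate cases", {
  n <- 200
  X <- std_markers(n, 150, seed = 81)
  D2 <- squared_distances(X)
  K1 <- gaussian_kernel(D2, 1)
  L <- t(chol(K1$values + diag(1e-8, n)))
  set.seed(11)
  hits <- 0
  for (rep in 1:20) {
    y <- as.numeric(L %*% rnorm(n)) * sqrt(0.8) + rnorm(n) * sqrt(0.2)
    h <- estimate_bandwidth(y, D2)$h
    hits <- hits + (h >= 1 / 3 && h <= 3)
  }
  expect_gte(hits / 20, 0.9)   # within a factor of 3 of the true h = 1

  # pure noise: flat criterion with a warning, still returns one h
  set.seed(12)
  expect_warning(flat <- estimate_bandwidth(rnorm(n), D2), "flat")
  expect_length(flat$h, 1)
  expect_true(flat$flat)

  # degenerate grid of length 1
  set.seed(13)
  one <- suppressWarnings(estimate_bandwidth(rnorm(n), D2, grid = 0.7))
  expect_equal(one$h, 0.7)
})
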