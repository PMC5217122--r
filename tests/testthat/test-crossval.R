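test_that("CV2 partitions have the exact training count, line coverage, and are seeded", {
  tab <- phenotype_table(matrix(rnorm(40), 10, 4,
                                dimnames = list(paste0("L", 1:10), paste0("E", 1:4))))
  parts <- make_cv2_partitions(tab, 0.7, 5, seed = 3)
  expect_length(parts, 5)
  for (p in parts) expect_equal(sum(p$mask), 28)     # 0.7 * 40

  # coverage property over 200 partitions at an awkward size
  tab2 <- phenotype_table(matrix(rnorm(34 * 3), 34, 3))
  many <- make_cv2_partitions(tab2, 0.7, 200, seed = 4)
  expect_true(all(vapply(many, function(p) sum(p$mask), 0L) ==
                    round(0.7 * 34 * 3)))
  expect_true(all(vapply(many, function(p) min(rowSums(p$mask)), 0) >= 1))

  again <- make_cv2_partitions(tab, 0.7, 5, seed = 3)
  other <- make_cv2_partitions(tab, 0.7, 5, seed = 99)
  expect_identical(lapply(parts, `[[`, "mask"), lapply(again, `[[`, "mask"))
  expect_false(identical(lapply(parts, `[[`, "mask"), lapply(other, `[[`, "mask")))

  expect_error(make_cv2_partitions(subset_env(tab, 1), 0.5, 1), "cannot cover")
  expect_error(make_cv2_partitions(tab, 1.2, 1), "train_fraction")
})

test_that("partitions respect the observed mask", {
  vals <- matrix(rnorm(60), 15, 4)
  obs <- matrix(TRUE, 15, 4); obs[cbind(1:6, c(1, 2, 3, 4, 1, 2))] <- FALSE
  tab <- phenotype_table(vals, observed = obs)
  parts <- make_cv2_partitions(tab, 0.7, 20, seed = 5)
  for (p in parts) {
    expect_true(all(!p$mask[!obs]))                  # training only at observed cells
    expect_equal(sum(p$mask), round(0.7 * sum(obs)))
  }
})

test_that("pearson_by_env matches hand-computed correlations and flags degeneracy", {
  tab <- phenotype_table(matrix(c(1, 2, 3, 4, 5, 4, 3, 2), 4, 2,
                                dimnames = list(paste0("L", 1:4), c("E1", "E2"))))
  part <- structure(list(mask = matrix(FALSE, 4, 2), partition_id = 1L, seed = 1L),
                    class = "cv_partition")
  part$mask[1, 2] <- TRUE                            # keep line coverage plausible
  pred <- tab$values
  r <- pearson_by_env(tab, pred, part)
  expect_equal(unname(r[["E1"]]), 1)
  r_neg <- pearson_by_env(tab, -pred, part)
  expect_equal(unname(r_neg[["E1"]]), -1)

  # hand value: obs (1,2,3,4) vs pred (2,1,4,3) -> r = 0.6
  pred2 <- pred; pred2[, 1] <- c(2, 1, 4, 3)
  expect_equal(unname(pearson_by_env(tab, pred2, part)[["E1"]]), 0.6)

  # zero variance -> NA with a warning, never a silent 0
  pred3 <- pred; pred3[, 1] <- 7
  expect_warning(r0 <- pearson_by_env(tab, pred3, part), "zero variance")
  expect_true(is.na(r0[["E1"]]))
})

test_that("a toy experiment produces correct bookkeeping and aggregation", {
  d <- toy_multienv(n = 30, m = 2, seed = 61)
  parts <- make_cv2_partitions(d$table, 0.7, 2, seed = 62)
  ex <- run_cv_experiment(d$table, list(gblup = d$K), models = 1,
                          partitions = parts,
                          mcmc = mcmc_config(600, 100, 2, seed = 63))
  expect_equal(nrow(ex$summary), 2)                  # m rows for one model/method
  expect_true(all(ex$summary$n_partitions == 2))
  # aggregation identity against the long table
  for (i in seq_len(nrow(ex$summary))) {
    sub <- ex$long[ex$long$env == ex$summary$env[i] &
                     ex$long$model == ex$summary$model[i], ]
    expect_equal(ex$summary$mean_r[i], mean(sub$r))
    expect_equal(ex$summary$sd_r[i], sd(sub$r))
  }
})

test_that("under train-only standardization a perturbed test cell cannot touch the fit", {
  d <- toy_multienv(n = 25, m = 2, seed = 64)
  part <- make_cv2_partitions(d$table, 0.7, 1, seed = 65)[[1]]
  test_cell <- which(d$table$observed & !part$mask)[1]
  vals2 <- d$table$values
  vals2[test_cell] <- vals2[test_cell] + 50
  tab2 <- phenotype_table(vals2, d$table$line_ids, d$table$env_ids)

  cfg <- mcmc_config(500, 100, 2, seed = 66)
  fit_of <- function(tab) {
    st <- standardize_phenotypes(tab, use = part$mask)
    masked <- phenotype_table(st$values, st$line_ids, st$env_ids,
                              observed = st$observed & part$mask)
    fit_multi(masked, d$K, include_f = FALSE, mcmc = cfg)
  }
  expect_identical(fit_of(d$table)$draws, fit_of(tab2)$draws)
})

test_that("percent change tables round half away from zero", {
  s <- data.frame(model = c(1, 2), method = "gblup", env = "E1",
                  mean_r = c(0.600, 0.615), sd_r = 0.01, n_partitions = 5)
  class(s) <- c("prediction_summary", "data.frame")
  pc <- percent_change(s, 2, "gblup", 1, "gblup")
  expect_equal(pc$percent_change, 3)                 # 2.5% rounds away from zero
  s$mean_r <- c(0.600, 0.585)
  expect_equal(percent_change(s, 2, "gblup", 1, "gblup")$percent_change, -3)
  expect_error(percent_change(s, 3, "gk", 1, "gblup"), "no rows")
})
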