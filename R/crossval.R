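# CV2 cross-validation: every line stays observed in at least one environment
# and is predicted in the environments where it was masked out.

#' Generate CV2 training/testing partitions
#'
#' Each partition selects \code{round(train_fraction * n_cells)} training cells
#' uniformly at random among the observed cells of the grid, subject to the
#' CV2 constraint that every line keeps at least one training cell. When a
#' sampled mask leaves a line uncovered, one of that line's cells is moved
#' into training and, to preserve the exact training count, a random training
#' cell of a maximally covered line is moved out.
#'
#' @param table a \code{phenotype_table}.
#' @param train_fraction fraction of cells assigned to training (default 0.7).
#' @param n_partitions number of random partitions (default 50).
#' @param seed RNG seed; partitions are deterministic given the seed.
#' @return a list of \code{cv_partition} objects, each with a logical n x m
#'   \code{mask} (\code{TRUE} = training cell), \code{partition_id} and
#'   \code{seed}.
#' @export
make_cv2_partitions <- function(table, train_fraction = 0.7, n_partitions = 50,
                                seed = 1L) {
  stopifnot(inherits(table, "phenotype_table"))
  if (train_fraction <= 0 || train_fraction >= 1) stop("train_fraction must be in (0, 1)")
  obs <- table$observed
  n <- nrow(obs); m <- ncol(obs)
  cells <- which(obs)
  n_train <- round(train_fraction * length(cells))
  if (n_train < n)
    stop("train_fraction too small: ", n_train, " training cells cannot cover ",
         n, " lines")
  .with_seed(seed, lapply(seq_len(n_partitions), function(pid) {
    mask <- matrix(FALSE, n, m, dimnames = dimnames(obs))
    mask[sample(cells, n_train)] <- TRUE
    repeat {
      uncovered <- which(rowSums(mask) == 0)
      if (length(uncovered) == 0) break
      i <- uncovered[1]
      from <- which(obs[i, ])
      j <- if (length(from) == 1) from else sample(from, 1)
      mask[i, j] <- TRUE
      cover <- rowSums(mask)
      donor_lines <- which(cover == max(cover))
      donor <- if (length(donor_lines) == 1) donor_lines else sample(donor_lines, 1)
      dj <- which(mask[donor, ])
      dj <- if (length(dj) == 1) dj else sample(dj, 1)
      mask[donor, dj] <- FALSE
    }
    structure(list(mask = mask, partition_id = pid, seed = as.integer(seed)),
              class = "cv_partition")
  }))
}

#' Per-environment prediction ability
#'
#' Pearson correlation between predicted and observed values over the test
#' cells (observed cells excluded from training) of each environment.
#'
#' @param obs a \code{phenotype_table} holding the observed values.
#' @param pred n x m matrix of predicted values (e.g. \code{predict()} of a
#'   \code{posterior_chain}).
#' @param partition a \code{cv_partition}.
#' @return named numeric vector of per-environment correlations; an
#'   environment whose test cells have zero variance (in observed or predicted
#'   values) yields \code{NA} with a warning, never a silent zero.
#' @export
pearson_by_env <- function(obs, pred, partition) {
  stopifnot(inherits(obs, "phenotype_table"), inherits(partition, "cv_partition"))
  pred <- as.matrix(pred)
  if (!identical(dim(pred), dim(obs$values))) stop("prediction grid dimension mismatch")
  test <- obs$observed & !partition$mask
  r <- stats::setNames(rep(NA_real_, ncol(pred)), obs$env_ids)
  for (j in seq_len(ncol(pred))) {
    idx <- which(test[, j])
    if (length(idx) < 3) {
      warning("environment ", obs$env_ids[j], " has fewer than 3 test cells")
      next
    }
    yo <- obs$values[idx, j]; yp <- pred[idx, j]
    if (stats::sd(yo) == 0 || stats::sd(yp) == 0) {
      warning("zero variance in test cells of environment ", obs$env_ids[j],
              "; correlation undefined")
      next
    }
    r[j] <- stats::cor(yo, yp)
  }
  r
}

# Mask test cells out of a phenotype table (they become unobserved).
.mask_table <- function(table, partition) {
  phenotype_table(table$values, table$line_ids, table$env_ids,
                  observed = table$observed & partition$mask,
                  standardization = table$standardization)
}

#' Run a CV2 prediction-ability experiment
#'
#' For every (model, kernel method, partition) combination: masks the test
#' cells, fits the model on the training cells, predicts the full grid and
#' computes per-environment Pearson correlations on the test cells. Model 1
#' fits each environment separately (the single-environment 70/30 scheme);
#' models 2 and 3 are the multi-environment fits without and with the extra
#' effect f.
#'
#' @param table a \code{phenotype_table} (typically standardized per
#'   environment).
#' @param kernels named list of \code{kernel_matrix} objects, e.g.
#'   \code{list(gblup = K_linear, gk = K_gaussian)}.
#' @param models integer subset of \code{c(1, 2, 3)}.
#' @param partitions list from \code{\link{make_cv2_partitions}}.
#' @param mcmc an \code{\link{mcmc_config}}; the seed is offset per fit so
#'   chains are independent yet reproducible.
#' @param prior optional \code{prior_spec} override (default: the package's
#'   data-driven single-environment rule and identity-scale multi-environment
#'   rule).
#' @param standardize_on \code{"full"} (default): each environment is
#'   standardized once on all its observed cells before partitioning (a no-op
#'   if the table already carries a standardization record) -- the convention
#'   of the multi-environment analyses this package emulates, with the
#'   attendant train/test leakage of two scalar constants documented in the
#'   methods vignette; or \code{"train"}: re-standardize each environment per
#'   partition using training cells only, so no test-cell information can
#'   reach the fit.
#' @return a list of class \code{cv_experiment}: \code{summary} (a
#'   \code{prediction_summary} data frame with mean r, SD and partition count
#'   per model/method/environment) and \code{long} (per-partition
#'   correlations). Failed fits are recorded with \code{NA} and a warning,
#'   never silently dropped.
#' @export
run_cv_experiment <- function(table, kernels, models = c(1, 2, 3), partitions,
                              mcmc = mcmc_config(), prior = NULL,
                              standardize_on = c("full", "train")) {
  stopifnot(inherits(table, "phenotype_table"), is.list(partitions))
  standardize_on <- match.arg(standardize_on)
  if (is.null(names(kernels)) || any(names(kernels) == ""))
    stop("kernels must be a named list (e.g. gblup, gk)")
  models <- sort(unique(as.integer(models)))
  if (!all(models %in% 1:3)) stop("models must be a subset of 1:3")
  m <- ncol(table$values)
  if (any(models > 1) && m < 2) stop("multi-environment models require m >= 2")

  if (standardize_on == "full" && is.null(table$standardization))
    table <- standardize_phenotypes(table)

  rows <- list()
  for (p_i in seq_along(partitions)) {
    part <- partitions[[p_i]]
    tab_p <- if (standardize_on == "train")
      standardize_phenotypes(table, use = part$mask) else table
    train_tab <- .mask_table(tab_p, part)
    for (meth in names(kernels)) {
      K <- kernels[[meth]]
      for (mod in models) {
        fit_seed <- mcmc$seed + 1000L * p_i + 10L * mod + match(meth, names(kernels))
        cfg <- mcmc_config(mcmc$iterations, mcmc$burn_in, mcmc$thin,
                           seed = fit_seed, store_effects = FALSE)
        pred <- tryCatch({
          if (mod == 1) {
            yh <- matrix(NA_real_, nrow(table$values), m)
            for (j in seq_len(m)) {
              fj <- fit_single(subset_env(train_tab, j), K,
                               prior = prior, mcmc = cfg)
              yh[, j] <- fj$yhat[, 1]
            }
            yh
          } else {
            fit_multi(train_tab, K, include_f = (mod == 3),
                      prior = prior, mcmc = cfg)$yhat
          }
        }, error = function(e) {
          warning("fit failed (partition ", p_i, ", model ", mod, ", ", meth,
                  "): ", conditionMessage(e))
          NULL
        })
        r <- if (is.null(pred)) stats::setNames(rep(NA_real_, m), table$env_ids)
             else pearson_by_env(tab_p, pred, part)
        rows[[length(rows) + 1L]] <- data.frame(
          partition = part$partition_id, model = mod, method = meth,
          env = table$env_ids, r = as.numeric(r),
          n_test = colSums(table$observed & !part$mask),
          stringsAsFactors = FALSE)
      }
    }
  }
  long <- do.call(rbind, rows)
  summary <- stats::aggregate(r ~ model + method + env, data = long,
                              FUN = function(x) c(mean = mean(x, na.rm = TRUE),
                                                  sd = stats::sd(x, na.rm = TRUE),
                                                  n = sum(!is.na(x))),
                              na.action = stats::na.pass)
  summary <- cbind(summary[, c("model", "method", "env")],
                   mean_r = summary$r[, "mean"], sd_r = summary$r[, "sd"],
                   n_partitions = summary$r[, "n"])
  summary <- summary[order(summary$model, summary$method, summary$env), ]
  rownames(summary) <- NULL
  class(summary) <- c("prediction_summary", "data.frame")
  structure(list(summary = summary, long = long), class = "cv_experiment")
}

#' Percent-change comparison table
#'
#' Computes 100 (r_A - r_B) / r_B per environment between two
#' (model, method) cells of a prediction summary, rounded half away from zero
#' to integer percent (the presentation convention of multi-environment
#' prediction studies).
#'
#' @param summary a \code{prediction_summary}.
#' @param model_a,method_a numerator configuration.
#' @param model_b,method_b baseline configuration.
#' @return data frame with environment and integer percent change.
#' @export
percent_change <- function(summary, model_a, method_a, model_b, method_b) {
  pick <- function(mod, meth) {
    s <- summary[summary$model == mod & summary$method == meth, ]
    if (nrow(s) == 0) stop("no rows for model ", mod, ", method ", meth)
    stats::setNames(s$mean_r, s$env)
  }
  a <- pick(model_a, method_a); b <- pick(model_b, method_b)
  envs <- intersect(names(a), names(b))
  data.frame(env = envs,
             percent_change = .round_half_away(100 * (a[envs] - b[envs]) / b[envs]),
             row.names = NULL, stringsAsFactors = FALSE)
}
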