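#' Marker quality control and standardization
#'
#' Drops markers with minor allele frequency below \code{maf_threshold}
#' (computed on observed calls only, before imputation) or with zero variance,
#' imputes remaining missing genotypes, and centers/scales each surviving
#' column to mean 0 and population SD 1 (divide by n, not n-1; under this
#' convention the linear kernel X X'/p has mean diagonal approximately 1).
#'
#' @param raw a raw \code{marker_matrix} with 0/1/2 dosage codes, NA allowed.
#' @param maf_threshold minimum minor allele frequency in [0, 0.5).
#' @param impute_mode \code{"mean"} replaces missing calls with the column mean
#'   of observed calls; \code{"bernoulli_draw"} samples from the column's
#'   empirical marginal genotype distribution.
#' @param seed integer seed used for \code{"bernoulli_draw"} imputation.
#' @return a standardized \code{marker_matrix} with attribute \code{"qc_report"},
#'   a data frame listing every dropped marker and the reason.
#' @export
standardize_markers <- function(raw, maf_threshold = 0.05,
                                impute_mode = c("mean", "bernoulli_draw"),
                                seed = 1L) {
  stopifnot(inherits(raw, "marker_matrix"))
  impute_mode <- match.arg(impute_mode)
  if (raw$is_standardized) stop("input is already standardized")
  if (maf_threshold < 0 || maf_threshold >= 0.5)
    stop("maf_threshold must lie in [0, 0.5)")
  X <- raw$values
  all_missing_line <- rowSums(!is.na(X)) == 0
  if (any(all_missing_line))
    stop("line(s) with all genotypes missing: ",
         paste(raw$line_ids[all_missing_line], collapse = ", "))

  n_obs <- colSums(!is.na(X))
  freq <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  drop_all_na <- n_obs == 0
  drop_zero_var <- !drop_all_na & (is.na(v) | v == 0)
  drop_maf <- !drop_all_na & !drop_zero_var & maf < maf_threshold

  reason <- rep(NA_character_, ncol(X))
  reason[drop_all_na] <- "all_missing"
  reason[drop_zero_var] <- "zero_variance"
  reason[drop_maf] <- "maf_below_threshold"
  dropped <- !is.na(reason)
  report <- data.frame(marker_id = raw$marker_ids[dropped],
                       reason = reason[dropped],
                       maf = maf[dropped], row.names = NULL,
                       stringsAsFactors = FALSE)
  if (all(dropped)) stop("no markers survive QC")

  X <- X[, !dropped, drop = FALSE]
  if (anyNA(X)) {
    X <- .with_seed(seed, {
      for (k in which(colSums(is.na(X)) > 0)) {
        obs <- X[!is.na(X[, k]), k]
        miss <- which(is.na(X[, k]))
        X[miss, k] <- if (impute_mode == "mean") mean(obs)
                      else sample(obs, length(miss), replace = TRUE)
      }
      X
    })
  }
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2, mu)^2))
  # bernoulli_draw can collapse a column to a constant; such columns are dropped too
  degenerate <- sd_pop == 0
  if (any(degenerate)) {
    report <- rbind(report, data.frame(marker_id = colnames(X)[degenerate],
                                       reason = "zero_variance_after_imputation",
                                       maf = NA_real_, stringsAsFactors = FALSE))
    X <- X[, !degenerate, drop = FALSE]
    mu <- mu[!degenerate]; sd_pop <- sd_pop[!degenerate]
    if (ncol(X) == 0) stop("no markers survive QC")
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sd_pop, "/")
  out <- marker_matrix(Xs, raw$line_ids, colnames(X), is_standardized = TRUE)
  attr(out, "qc_report") <- report
  out
}

#' Linear (GBLUP) kernel
#'
#' Computes the genomic relationship matrix K = X X' / p from a standardized
#' marker matrix.
#'
#' @param X a standardized \code{marker_matrix}.
#' @return a \code{kernel_matrix} of kind \code{"linear"}.
#' @export
linear_kernel <- function(X) {
  stopifnot(inherits(X, "marker_matrix"))
  if (!X$is_standardized) stop("linear_kernel requires a standardized marker matrix")
  p <- ncol(X$values)
  if (p < 1) stop("at least one marker required")
  K <- .symmetrize(tcrossprod(X$values) / p)
  kernel_matrix(K, X$line_ids, kind = "linear")
}

#' Squared marker distances between lines
#'
#' Pairwise squared Euclidean distances on standardized markers, optionally
#' divided by an off-diagonal summary (median by default) so that a bandwidth
#' of h = 1 is a natural center for the Gaussian-kernel search grid regardless
#' of data-set size.
#'
#' @param X a standardized \code{marker_matrix}.
#' @param scale \code{"median"} (default), \code{"mean"}, or \code{"none"}.
#' @return an n x n matrix with zero diagonal; attributes
#'   \code{"distance_scale"} (the divisor used) and \code{"scale_method"}.
#' @export
squared_distances <- function(X, scale = c("median", "mean", "none")) {
  stopifnot(inherits(X, "marker_matrix"))
  scale <- match.arg(scale)
  if (!X$is_standardized) stop("squared_distances requires a standardized marker matrix")
  n <- nrow(X$values)
  D2 <- as.matrix(stats::dist(X$values))^2
  diag(D2) <- 0
  D2 <- .symmetrize(D2)
  sc <- 1
  if (scale != "none") {
    if (n < 2) stop("scaling requires at least 2 lines (no off-diagonal entries)")
    off <- D2[upper.tri(D2)]
    sc <- if (scale == "median") stats::median(off) else mean(off)
    if (sc <= 0) stop("off-diagonal distance summary is zero; cannot scale")
    D2 <- D2 / sc
  }
  dimnames(D2) <- list(X$line_ids, X$line_ids)
  attr(D2, "distance_scale") <- sc
  attr(D2, "scale_method") <- scale
  D2
}

#' Gaussian kernel
#'
#' Entrywise K = exp(-h d^2) on a squared-distance matrix; the diagonal is
#' exactly 1 and all entries lie in (0, 1].
#'
#' @param D2 symmetric nonnegative matrix with zero diagonal (see
#'   \code{\link{squared_distances}}).
#' @param h positive bandwidth.
#' @return a \code{kernel_matrix} of kind \code{"gaussian"}.
#' @export
gaussian_kernel <- function(D2, h) {
  if (!is.numeric(h) || length(h) != 1 || h <= 0) stop("bandwidth h must be > 0")
  D2 <- as.matrix(D2)
  if (any(D2 < 0)) stop("squared distances must be nonnegative")
  if (max(abs(diag(D2))) > 0) stop("squared-distance matrix must have zero diagonal")
  K <- exp(-h * D2)
  diag(K) <- 1
  attr(K, "distance_scale") <- NULL
  attr(K, "scale_method") <- NULL
  kernel_matrix(.symmetrize(K), rownames(D2), kind = "gaussian", bandwidth = h,
                distance_scale = attr(D2, "distance_scale"))
}

#' Bandwidth estimation for the Gaussian kernel
#'
#' Selects the bandwidth h maximizing the log marginal likelihood of the
#' single-environment kernel regression y = 1 mu + u + e, u ~ N(0, su2 K(h)),
#' with the intercept and the error variance profiled out analytically and the
#' variance ratio su2/se2 profiled over an inner grid. This is a documented
#' stand-in for the empirical-Bayes bandwidth procedure the package emulates;
#' it is deterministic given its inputs.
#'
#' @param y a one-environment \code{phenotype_table} (complete for that
#'   environment) or a numeric vector.
#' @param D2 squared-distance matrix from \code{\link{squared_distances}}.
#' @param grid candidate bandwidths (positive).
#' @param ratio_grid inner grid of su2/se2 ratios.
#' @return a list with \code{h} (the maximizer), \code{criterion} (a data frame
#'   of grid point, best ratio, and log marginal likelihood) and \code{flat}
#'   (TRUE when the criterion is flat across the grid, i.e. no genetic signal
#'   localizes h; a warning is raised in that case).
#' @export
estimate_bandwidth <- function(y, D2,
                               grid = c(0.1, 0.25, 0.5, 1, 2, 4, 10),
                               ratio_grid = exp(seq(log(0.02), log(500), length.out = 25))) {
  if (inherits(y, "phenotype_table")) {
    if (ncol(y$values) != 1) stop("estimate_bandwidth expects a single environment")
    if (!all(y$observed)) stop("phenotypes must be complete for bandwidth estimation")
    y <- as.numeric(y$values[, 1])
  }
  y <- as.numeric(y)
  if (length(grid) == 0 || any(grid <= 0)) stop("grid must be nonempty and positive")
  n <- length(y)
  if (nrow(as.matrix(D2)) != n) stop("D2 order must match length(y)")
  ones <- rep(1, n)
  crit <- data.frame(h = grid, ratio = NA_real_, log_ml = NA_real_)
  for (gi in seq_along(grid)) {
    K <- exp(-grid[gi] * as.matrix(D2)); diag(K) <- 1
    e <- .eigen_kernel(K)
    yt <- crossprod(e$vectors, y)
    ot <- crossprod(e$vectors, ones)
    best <- -Inf; best_r <- NA_real_
    for (r in ratio_grid) {
      w <- 1 / (r * e$values + 1)            # proportional precision weights
      mu <- sum(w * ot * yt) / sum(w * ot^2)  # profiled GLS intercept
      q <- sum(w * (yt - mu * ot)^2)
      s2 <- q / n                             # profiled error variance
      ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(r * e$values + 1)) + n)
      if (is.finite(ll) && ll > best) { best <- ll; best_r <- r }
    }
    crit$log_ml[gi] <- best; crit$ratio[gi] <- best_r
  }
  if (all(!is.finite(crit$log_ml))) stop("bandwidth criterion non-finite for every grid point")
  # flatness: gain of the best (h, ratio) pair over the exact iid null model
  # (ratio -> 0), on the likelihood-ratio scale; < 2 log units means no genetic
  # signal localizes h
  s2_null <- mean((y - mean(y))^2)
  ll_null <- -0.5 * n * (log(2 * pi * s2_null) + 1)
  flat <- (max(crit$log_ml) - ll_null) < 2
  if (flat) warning("bandwidth criterion is nearly flat across the grid; ",
                    "no genetic signal localizes h")
  list(h = crit$h[which.max(crit$log_ml)], criterion = crit, flat = flat)
}
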