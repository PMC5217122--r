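# Synthetic marker and multi-environment phenotype generation with the exact
# covariance structure of the fitted models, so that round-trip parameter
# recovery is a cross-module consistency test of generator and sampler alike.

#' Simulate a biallelic marker matrix
#'
#' Each marker's allele frequency is drawn uniformly from \code{maf_range} and
#' line genotypes are independent Binomial(2, freq) dosages -- the structure of
#' DArT/GBS dosage panels without linkage disequilibrium or stratification.
#'
#' @param n,p numbers of lines and markers (>= 2 each).
#' @param maf_range allele-frequency interval within (0, 0.5].
#' @param seed RNG seed.
#' @return a raw \code{marker_matrix}.
#' @export
simulate_markers <- function(n, p, maf_range = c(0.05, 0.5), seed = 1L) {
  n <- .stopifnot_count(n, "n"); p <- .stopifnot_count(p, "p")
  if (n < 2 || p < 2) stop("n and p must be >= 2")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  .with_seed(seed, {
    freq <- stats::runif(p, maf_range[1], maf_range[2])
    X <- matrix(stats::rbinom(n * p, 2, rep(freq, each = n)), n, p)
    marker_matrix(X,
                  line_ids = sprintf("L%04d", seq_len(n)),
                  marker_ids = sprintf("M%05d", seq_len(p)))
  })
}

#' Simulation scenario
#'
#' Describes a multi-environment trial world: n lines in m environments with p
#' markers, true between-environment genetic covariance \code{UE_true}, the
#' optional extra-effect covariance \code{FE_true}, per-environment residual
#' variances \code{Sigma_true}, and the genetic architecture (purely additive,
#' or additive plus sparse pairwise marker-product epistasis, under which the
#' linear kernel is misspecified while the Gaussian kernel can adapt).
#'
#' @param n,m,p counts (defaults emulate a CIMMYT-scale trial: 500 lines, 4
#'   environments, 2000 markers).
#' @param maf_range marker allele-frequency interval.
#' @param UE_true m x m positive-definite genetic covariance.
#' @param FE_true m x m positive-definite covariance of the non-marker effect,
#'   or \code{NULL} to omit it.
#' @param Sigma_true length-m positive residual variances.
#' @param mu_true length-m intercepts (default 0, matching standardized data).
#' @param architecture \code{"additive"} or \code{"epistatic"}.
#' @param epi_share fraction of genetic variance from pairwise products under
#'   the epistatic architecture (default 0.5).
#' @param seed RNG seed.
#' @return an object of class \code{simulation_scenario}.
#' @export
simulation_scenario <- function(n = 500, m = 4, p = 2000,
                                maf_range = c(0.05, 0.5),
                                UE_true = diag(0.7, m) + 0.0,
                                FE_true = NULL,
                                Sigma_true = rep(0.3, m),
                                mu_true = rep(0, m),
                                architecture = c("additive", "epistatic"),
                                epi_share = 0.5, seed = 1L) {
  architecture <- match.arg(architecture)
  UE_true <- as.matrix(UE_true)
  .check_pd(UE_true, "UE_true")
  if (nrow(UE_true) != m) stop("UE_true must be m x m")
  if (!is.null(FE_true)) {
    FE_true <- as.matrix(FE_true)
    if (nrow(FE_true) != m) stop("FE_true order does not match m")
    .check_pd(FE_true, "FE_true")
  }
  if (length(Sigma_true) != m || any(Sigma_true <= 0))
    stop("Sigma_true must be m positive variances")
  if (epi_share < 0 || epi_share > 1) stop("epi_share must be in [0, 1]")
  structure(list(n = n, m = m, p = p, maf_range = maf_range,
                 UE_true = UE_true, FE_true = FE_true,
                 Sigma_true = as.numeric(Sigma_true), mu_true = as.numeric(mu_true),
                 architecture = architecture, epi_share = epi_share,
                 seed = as.integer(seed)), class = "simulation_scenario")
}

# Cholesky factors for the epistatic architecture: additive component from the
# linear kernel K = X X'/p, interaction component from the Hadamard square
# K o K -- the covariance of genetic values carrying i.i.d. effects on *all*
# pairwise marker products (dense limit). A sparse random subset of pairs is
# statistically invisible to any kernel at desk scale, so the dense limit is
# used; it is exactly the second-order similarity a Gaussian kernel contains
# and a linear kernel does not.
.epistatic_factors <- function(Xs) {
  Kv <- tcrossprod(Xs) / ncol(Xs)
  list(La = t(.chol_jitter(Kv + diag(1e-6 * mean(diag(Kv)), nrow(Kv)), "K")),
       Le = t(.chol_jitter(Kv * Kv + diag(1e-6, nrow(Kv)), "K o K")))
}

.epistatic_value <- function(fac, epi_share) {
  n <- nrow(fac$La)
  scale01 <- function(v) { s <- stats::sd(v); if (s == 0) v else (v - mean(v)) / s }
  add <- scale01(fac$La %*% stats::rnorm(n))
  epi <- scale01(fac$Le %*% stats::rnorm(n))
  # rescale the mixture: the two components are only asymptotically orthogonal,
  # so the raw sum's variance drifts from 1 at finite n
  as.numeric(scale01(sqrt(1 - epi_share) * add + sqrt(epi_share) * epi))
}

#' Simulate multi-environment phenotypes
#'
#' Draws Y = mu + U + F + E on the scenario's n x m grid. Under the additive
#' architecture U is a matrix-normal draw with row covariance K and column
#' covariance \code{UE_true} -- exactly the model the multi-environment sampler
#' assumes. Under the epistatic architecture each latent genetic column is
#' a mixture of an additive draw (covariance K) and a pairwise-interaction draw
#' (covariance K o K, the dense all-pairs product-effect limit), and the
#' columns are mixed through the Cholesky factor of \code{UE_true}, so
#' cross-environment covariance is preserved while the linear kernel is
#' misspecified. F rows are i.i.d. N(0, FE_true); E is independent
#' per-cell noise.
#'
#' @param scenario a \code{simulation_scenario}.
#' @param K a \code{kernel_matrix} (additive architecture), typically built
#'   from markers simulated under the same scenario.
#' @param X a standardized \code{marker_matrix} (required for the epistatic
#'   architecture).
#' @return a list with \code{table} (a fully observed \code{phenotype_table})
#'   and \code{truth} (U, F, E, mu and the scenario).
#' @export
simulate_multienv_phenotypes <- function(scenario, K = NULL, X = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  n <- scenario$n; m <- scenario$m
  .with_seed(scenario$seed + 7L, {
    if (scenario$architecture == "additive") {
      if (is.null(K)) stop("additive architecture requires a kernel K")
      Kv <- if (inherits(K, "kernel_matrix")) K$values else as.matrix(K)
      if (nrow(Kv) != n) stop("kernel order does not match scenario n")
      Lk <- t(.chol_jitter(Kv, "K"))
      U <- Lk %*% matrix(stats::rnorm(n * m), n, m) %*% chol(scenario$UE_true)
      line_ids <- if (inherits(K, "kernel_matrix")) K$line_ids else rownames(Kv)
    } else {
      if (is.null(X) || !inherits(X, "marker_matrix") || !X$is_standardized)
        stop("epistatic architecture requires a standardized marker_matrix X")
      if (nrow(X$values) != n) stop("marker matrix order does not match scenario n")
      fac <- .epistatic_factors(X$values)
      G <- vapply(seq_len(m), function(j) .epistatic_value(fac, scenario$epi_share),
                  numeric(n))
      U <- G %*% chol(scenario$UE_true)
      line_ids <- X$line_ids
    }
    if (is.null(line_ids)) line_ids <- sprintf("L%04d", seq_len(n))
    Fm <- if (is.null(scenario$FE_true)) matrix(0, n, m)
          else matrix(stats::rnorm(n * m), n, m) %*% chol(scenario$FE_true)
    E <- matrix(stats::rnorm(n * m), n, m) * rep(sqrt(scenario$Sigma_true), each = n)
    Y <- rep(scenario$mu_true, each = n) + U + Fm + E
    env_ids <- paste0("E", seq_len(m))
    dimnames(Y) <- list(line_ids, env_ids)
    list(table = phenotype_table(Y, line_ids, env_ids),
         truth = list(U = U, F = Fm, E = E, mu = scenario$mu_true,
                      scenario = scenario))
  })
}

#' Load a scenario preset
#'
#' Presets ship as JSON files under \code{inst/extdata/scenarios/} and emulate
#' the structure of published CIMMYT trials (e.g. \code{"wheat1_like"}: 4
#' environments with one negatively correlated with the rest;
#' \code{"maize2_like"}: 3 moderately positively correlated environments).
#'
#' @param scenario preset name or a path to a JSON/YAML scenario file.
#' @param ... overrides passed to \code{\link{simulation_scenario}} (e.g.
#'   \code{n}, \code{p}, \code{seed}) taking precedence over the preset.
#' @return a \code{simulation_scenario}.
#' @export
load_scenario <- function(scenario, ...) {
  path <- if (file.exists(scenario)) scenario
          else system.file("extdata", "scenarios", paste0(scenario, ".json"),
                           package = "kernelgxe")
  if (path == "" || !file.exists(path)) stop("unknown scenario: ", scenario)
  spec <- if (grepl("\\.ya?ml$", path)) .read_yaml_file(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  spec$UE_true <- matrix(unlist(spec$UE_true), spec$m, spec$m)
  if (!is.null(spec$FE_true)) spec$FE_true <- matrix(unlist(spec$FE_true), spec$m, spec$m)
  over <- list(...)
  spec[names(over)] <- over
  do.call(simulation_scenario, spec)
}
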