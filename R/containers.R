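#' Marker genotype matrix
#'
#' Container for an n x p genotype matrix (lines x markers). Raw matrices hold
#' biallelic dosage codes 0/1/2 (missing allowed); standardized matrices hold
#' real values with every column centered to mean 0 and scaled to population
#' standard deviation 1 (the convention under which the mean diagonal of the
#' linear kernel X X' / p is approximately 1).
#'
#' @param values numeric matrix, lines in rows, markers in columns.
#' @param line_ids character vector of unique line identifiers (defaults to
#'   rownames of \code{values}).
#' @param marker_ids character vector of marker identifiers (defaults to
#'   colnames of \code{values}).
#' @param is_standardized logical flag; if \code{TRUE} column means/SDs and the
#'   absence of missing values are validated.
#' @return an object of class \code{marker_matrix}.
#' @export
marker_matrix <- function(values, line_ids = rownames(values),
                          marker_ids = colnames(values),
                          is_standardized = FALSE) {
  values <- as.matrix(values)
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(values)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(values)))
  line_ids <- as.character(line_ids)
  marker_ids <- as.character(marker_ids)
  if (length(line_ids) != nrow(values)) stop("line_ids length must match rows")
  if (length(marker_ids) != ncol(values)) stop("marker_ids length must match columns")
  if (anyDuplicated(line_ids)) stop("duplicated line_ids: ",
                                    paste(unique(line_ids[duplicated(line_ids)]), collapse = ", "))
  storage.mode(values) <- "double"
  dimnames(values) <- list(line_ids, marker_ids)
  obj <- structure(list(line_ids = line_ids, marker_ids = marker_ids,
                        values = values, is_standardized = isTRUE(is_standardized)),
                   class = "marker_matrix")
  if (obj$is_standardized) {
    if (anyNA(values)) stop("standardized marker matrix may not contain missing values")
    mu <- colMeans(values)
    sd_pop <- sqrt(colMeans(sweep(values, 2, mu)^2))
    if (any(abs(mu) > 1e-8)) stop("standardized columns must have mean 0")
    if (any(abs(sd_pop - 1) > 1e-8)) stop("standardized columns must have population SD 1")
  }
  obj
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d lines x %d markers (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_standardized) "standardized" else "raw"))
  invisible(x)
}

#' Genomic relationship kernel
#'
#' An n x n symmetric positive semi-definite relationship matrix between lines,
#' either the linear (GBLUP) kernel X X' / p, a Gaussian kernel
#' exp(-h d^2), or a user-supplied custom kernel.
#'
#' @param values symmetric numeric matrix.
#' @param line_ids line identifiers (defaults to rownames).
#' @param kind one of \code{"linear"}, \code{"gaussian"}, \code{"custom"}.
#' @param bandwidth positive bandwidth h (Gaussian kernels only).
#' @param distance_scale the off-diagonal summary the squared distances were
#'   divided by (Gaussian kernels only).
#' @return an object of class \code{kernel_matrix}.
#' @export
kernel_matrix <- function(values, line_ids = rownames(values),
                          kind = c("custom", "linear", "gaussian"),
                          bandwidth = NULL, distance_scale = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(values)))
  line_ids <- as.character(line_ids)
  if (length(line_ids) != nrow(values)) stop("line_ids length must match kernel order")
  if (!.is_symmetric(values, tol = 1e-10)) stop("kernel must be symmetric to 1e-10")
  ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev, 1e-12))
    stop("kernel is not positive semi-definite (min eigenvalue ", signif(min(ev), 3), ")")
  if (kind == "gaussian") {
    if (is.null(bandwidth) || bandwidth <= 0) stop("gaussian kernel requires bandwidth > 0")
    if (any(values <= 0) || any(values > 1 + 1e-12))
      stop("gaussian kernel entries must lie in (0, 1]")
    diag(values) <- 1
  }
  dimnames(values) <- list(line_ids, line_ids)
  structure(list(line_ids = line_ids, values = values, kind = kind,
                 bandwidth = bandwidth, distance_scale = distance_scale),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix (%s): %d lines, mean diagonal %.4f",
              x$kind, nrow(x$values), mean(diag(x$values))))
  if (!is.null(x$bandwidth)) cat(sprintf(", h = %g", x$bandwidth))
  cat("\n")
  invisible(x)
}

#' Multi-environment phenotype grid
#'
#' An n x m grid of phenotypic values (lines x environments) with an
#' observed/missing mask. Values at unobserved cells are ignored by all
#' likelihood computations.
#'
#' @param values numeric n x m matrix; \code{NA} marks unobserved cells unless
#'   \code{observed} is given explicitly.
#' @param line_ids,env_ids identifiers (default: dimnames).
#' @param observed logical n x m mask, \code{TRUE} = observed.
#' @param standardization optional data frame (env, mean, sd) recording a
#'   per-environment standardization already applied.
#' @return an object of class \code{phenotype_table}.
#' @export
phenotype_table <- function(values, line_ids = rownames(values),
                            env_ids = colnames(values), observed = NULL,
                            standardization = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(values)))
  if (is.null(env_ids)) env_ids <- paste0("E", seq_len(ncol(values)))
  line_ids <- as.character(line_ids); env_ids <- as.character(env_ids)
  if (anyDuplicated(line_ids)) stop("duplicated line_ids")
  if (anyDuplicated(env_ids)) stop("duplicated env_ids")
  if (is.null(observed)) observed <- !is.na(values)
  observed <- as.matrix(observed)
  if (!identical(dim(observed), dim(values))) stop("observed mask dimension mismatch")
  if (any(is.na(values) & observed)) stop("observed cells may not hold NA values")
  dimnames(values) <- dimnames(observed) <- list(line_ids, env_ids)
  structure(list(line_ids = line_ids, env_ids = env_ids, values = values,
                 observed = observed, standardization = standardization),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d lines x %d environments, %d/%d cells observed%s\n",
              nrow(x$values), ncol(x$values), sum(x$observed), length(x$observed),
              if (is.null(x$standardization)) "" else " (standardized)"))
  invisible(x)
}

#' Standardize phenotypes per environment
#'
#' Centers and scales each environment's observed values to mean 0, SD 1
#' (sample SD), recording the applied (mean, sd) so results can be mapped back
#' to the original scale. Cells in \code{use} only (e.g. training cells under
#' a cross-validation partition) can be used to estimate the constants, which
#' are then applied to the whole column.
#'
#' @param table a \code{phenotype_table}.
#' @param use optional logical mask restricting which observed cells inform the
#'   per-environment mean and SD (default: all observed cells).
#' @return a standardized \code{phenotype_table}.
#' @export
standardize_phenotypes <- function(table, use = NULL) {
  stopifnot(inherits(table, "phenotype_table"))
  if (is.null(use)) use <- table$observed else use <- use & table$observed
  vals <- table$values
  rec <- data.frame(env = table$env_ids, mean = NA_real_, sd = NA_real_)
  for (j in seq_along(table$env_ids)) {
    y <- vals[use[, j], j]
    if (length(y) < 2) stop("environment ", table$env_ids[j],
                            " has fewer than 2 usable cells for standardization")
    m <- mean(y); s <- stats::sd(y)
    if (s == 0) stop("environment ", table$env_ids[j], " has zero variance")
    vals[, j] <- (vals[, j] - m) / s
    rec$mean[j] <- m; rec$sd[j] <- s
  }
  phenotype_table(vals, table$line_ids, table$env_ids, observed = table$observed,
                  standardization = rec)
}

#' Extract a single environment
#'
#' @param table a \code{phenotype_table}.
#' @param env environment id or index.
#' @return a one-environment \code{phenotype_table}.
#' @export
subset_env <- function(table, env) {
  stopifnot(inherits(table, "phenotype_table"))
  j <- if (is.character(env)) match(env, table$env_ids) else as.integer(env)
  if (is.na(j) || j < 1 || j > length(table$env_ids)) stop("unknown environment: ", env)
  phenotype_table(table$values[, j, drop = FALSE], table$line_ids,
                  table$env_ids[j], observed = table$observed[, j, drop = FALSE],
                  standardization = if (is.null(table$standardization)) NULL
                                    else table$standardization[j, , drop = FALSE])
}
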