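# Readers and writers for marker, phenotype, kernel, partition, chain and
# summary files. All formats are plain text (CSV/TSV/JSON) and every writer's
# output is parsed back to equal values by its paired reader.

.read_yaml_file <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML requires the 'yaml' package; use the JSON format instead")
  yaml::read_yaml(path)
}

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a marker genotype file
#'
#' Accepts two dialects: (a) CSV/TSV with line ids in the first column and one
#' marker per remaining column (header row of marker ids); (b) PLINK RAW
#' (\code{--recode A}) with FID/IID/PAT/MAT/SEX/PHENOTYPE leading columns,
#' space- or tab-separated 0/1/2 dosages and \code{NA} for missing (IID is
#' used as line id).
#'
#' @param path file path.
#' @return a raw \code{marker_matrix}.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  header <- strsplit(trimws(readLines(path, n = 1L)), "[ \t,]+")[[1]]
  plink <- length(header) >= 6 &&
    all(toupper(header[1:6]) == c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  if (plink) {
    d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "-9"))
    X <- as.matrix(d[, -(1:6), drop = FALSE])
    storage.mode(X) <- "double"
    return(marker_matrix(X, line_ids = as.character(d$IID),
                         marker_ids = colnames(d)[-(1:6)]))
  }
  sep <- .detect_sep(path)
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  X <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  marker_matrix(X, line_ids = as.character(d[[1]]), marker_ids = colnames(d)[-1])
}

#' Write a marker matrix
#'
#' @param X a \code{marker_matrix}.
#' @param path output CSV path (first column \code{line_id}).
#' @export
write_markers <- function(X, path) {
  stopifnot(inherits(X, "marker_matrix"))
  d <- data.frame(line_id = X$line_ids, X$values, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype file
#'
#' Long dialect: columns \code{line_id}, \code{env_id}, \code{value} (one row
#' per observed cell; absent cells are unobserved). Wide dialect: line ids in
#' the first column, one environment per remaining column, \code{NA} for
#' unobserved cells. Line and environment ordering follow first appearance.
#'
#' @param path file path.
#' @param dialect \code{"long"} (default) or \code{"wide"}.
#' @return a \code{phenotype_table}.
#' @export
read_phenotypes <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  sep <- .detect_sep(path)
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("empty phenotype file: ", path)
  if (dialect == "wide") {
    vals <- as.matrix(d[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    return(phenotype_table(vals, line_ids = as.character(d[[1]]),
                           env_ids = colnames(d)[-1]))
  }
  if (!all(c("line_id", "env_id", "value") %in% colnames(d)))
    stop("long dialect requires columns line_id, env_id, value")
  if (!is.numeric(d$value)) stop("non-numeric phenotype values")
  key <- paste(d$line_id, d$env_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- d[duplicated(key), c("line_id", "env_id")][1, ]
    stop("duplicate phenotype cell: (", dup$line_id, ", ", dup$env_id, ")")
  }
  lines <- unique(as.character(d$line_id))
  envs <- unique(as.character(d$env_id))
  vals <- matrix(NA_real_, length(lines), length(envs),
                 dimnames = list(lines, envs))
  vals[cbind(match(d$line_id, lines), match(d$env_id, envs))] <- d$value
  phenotype_table(vals, lines, envs)
}

#' Write a phenotype table
#'
#' @param table a \code{phenotype_table}.
#' @param path output CSV path.
#' @param dialect \code{"long"} (observed cells only) or \code{"wide"}.
#' @export
write_phenotypes <- function(table, path, dialect = c("long", "wide")) {
  stopifnot(inherits(table, "phenotype_table"))
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    vals <- table$values
    vals[!table$observed] <- NA_real_
    d <- data.frame(line_id = table$line_ids, vals, check.names = FALSE)
  } else {
    idx <- which(table$observed, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    d <- data.frame(line_id = table$line_ids[idx[, 1]],
                    env_id = table$env_ids[idx[, 2]],
                    value = table$values[idx])
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a kernel matrix
#'
#' CSV with line ids as both header and first column; a JSON sidecar
#' (\code{<path>.meta.json}) records kind, bandwidth and distance scale so the
#' round trip is lossless.
#'
#' @param K a \code{kernel_matrix}.
#' @param path CSV path.
#' @export
write_kernel <- function(K, path) {
  stopifnot(inherits(K, "kernel_matrix"))
  d <- data.frame(line_id = K$line_ids, K$values, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  meta <- list(kind = K$kind, bandwidth = K$bandwidth,
               distance_scale = K$distance_scale,
               mean_diagonal = mean(diag(K$values)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_kernel
#' @return \code{read_kernel}: the \code{kernel_matrix}.
#' @export
read_kernel <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                         check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  vals <- .symmetrize(vals)  # guard against decimal-printing asymmetry
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE)
          else list(kind = "custom")
  kernel_matrix(vals, line_ids = as.character(d[[1]]), kind = meta$kind,
                bandwidth = meta$bandwidth, distance_scale = meta$distance_scale)
}

#' Write / read a prediction summary
#'
#' The full-precision CSV round-trips mean/SD/count exactly; alongside it a
#' display file (\code{<path>.display.csv}) shows "0.606 (0.037)"-style cells
#' (mean with SD in parentheses, 3 decimals).
#'
#' @param summary a \code{prediction_summary}.
#' @param path CSV path.
#' @export
write_summary <- function(summary, path) {
  stopifnot(is.data.frame(summary))
  d <- as.data.frame(summary)
  utils::write.csv(format(d, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  if (nrow(d) > 0) {
    disp <- d[, c("model", "method", "env")]
    disp$accuracy <- sprintf("%.3f (%.3f)", d$mean_r, d$sd_r)
  } else {
    disp <- data.frame(model = integer(), method = character(),
                       env = character(), accuracy = character())
  }
  utils::write.csv(disp, paste0(path, ".display.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @return \code{read_summary}: the \code{prediction_summary} data frame.
#' @export
read_summary <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) > 0) {
    d$model <- as.integer(d$model)
    d$mean_r <- as.numeric(d$mean_r); d$sd_r <- as.numeric(d$sd_r)
    d$n_partitions <- as.numeric(d$n_partitions)
  }
  class(d) <- c("prediction_summary", "data.frame")
  d
}

#' Write / read CV2 partitions
#'
#' One CSV per partition (\code{part_001.csv}, ...): a line x environment grid
#' of 0/1 training flags with line ids in the first column.
#'
#' @param partitions list of \code{cv_partition} objects.
#' @param dir output directory (created if needed).
#' @export
write_partitions <- function(partitions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in partitions) {
    d <- data.frame(line_id = rownames(p$mask), p$mask + 0L, check.names = FALSE)
    utils::write.csv(d, file.path(dir, sprintf("part_%03d.csv", p$partition_id)),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_partitions
#' @return \code{read_partitions}: the list of \code{cv_partition} objects.
#' @export
read_partitions <- function(dir) {
  files <- sort(list.files(dir, pattern = "^part_\\d+\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop("no partition files in ", dir)
  lapply(files, function(f) {
    d <- utils::read.csv(f, check.names = FALSE, stringsAsFactors = FALSE)
    mask <- as.matrix(d[, -1, drop = FALSE]) == 1
    rownames(mask) <- as.character(d[[1]])
    structure(list(mask = mask,
                   partition_id = as.integer(sub("^part_0*(\\d+)\\.csv$", "\\1", basename(f))),
                   seed = NA_integer_), class = "cv_partition")
  })
}

#' Write a posterior chain to disk
#'
#' Retained scalar/covariance draws go to \code{chain.csv} (one row per draw);
#' posterior means and effective sample sizes go to \code{summary.json}.
#'
#' @param chain a \code{posterior_chain}.
#' @param dir output directory.
#' @export
write_chain <- function(chain, dir) {
  stopifnot(inherits(chain, "posterior_chain"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(chain$draws), file.path(dir, "chain.csv"),
                   row.names = FALSE)
  summ <- list(model = chain$model, n_retained = chain$n_retained,
               ess = as.list(chain$ess),
               posterior_means = as.list(colMeans(chain$draws)))
  if (!is.null(chain$UE_mean)) summ$UE_mean <- chain$UE_mean
  if (!is.null(chain$FE_mean)) summ$FE_mean <- chain$FE_mean
  jsonlite::write_json(summ, file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' Load a run configuration
#'
#' JSON (or YAML, when the \code{yaml} package is available) mapping of run
#' settings. Unknown keys are rejected by name; referenced input files must
#' exist at load time.
#'
#' @param path configuration file.
#' @return a named list of settings with class \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) .read_yaml_file(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("phenotypes", "markers", "kernel", "models", "methods",
               "partitions", "train_fraction", "iterations", "burn_in", "thin",
               "seed", "bandwidth", "bandwidth_grid", "maf_threshold",
               "impute_mode", "out_dir", "log_level", "standardize_on")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (key in c("phenotypes", "markers", "kernel")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("config references missing file for '", key, "': ", cfg[[key]])
  }
  structure(cfg, class = c("run_config", "list"))
}
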