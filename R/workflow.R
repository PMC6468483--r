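#' Read a sample-by-variable matrix from CSV/TSV
#'
#' Expects the first column to hold sample identifiers and the header row the
#' variable identifiers; empty cells or "NA" are read as missing.
#'
#' @param path file path; the separator is taken from the extension
#'   (\code{.tsv}/\code{.txt} tab, otherwise comma) unless given.
#' @param sep field separator override.
#' @return numeric matrix with dimnames.
#' @export
read_data_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, na.strings = c("", "NA"))
  as.matrix(df)
}

#' Write a sample-by-variable matrix to CSV
#'
#' @param X matrix.
#' @param path output path.
#' @export
write_data_matrix <- function(X, path) {
  df <- data.frame(sample_id = rownames(X) %||% seq_len(nrow(X)),
                   as.data.frame(X), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Serialize a fitted PLS2 model to a directory of CSV matrices
#'
#' Writes W, Wstar, P, Q, T, U, B and both residual blocks as CSV files plus
#' a JSON metadata file with the component count, eigenvalues and the
#' pre-treatment parameters of both blocks. The directory round-trips through
#' [read_model()] with identical predictions.
#'
#' @param object a \code{"pls2"} (or constrained) model.
#' @param dir output directory (created if absent).
#' @export
write_model <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mats <- list(W = object$weights, Wstar = object$Wstar,
               P = object$x_loadings, Q = object$y_loadings,
               T = object$scores, U = object$y_scores, B = object$coefficients,
               E = object$residuals$X, F = object$residuals$Y)
  for (nm in names(mats))
    utils::write.csv(mats[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  meta <- list(class = class(object), ncomp = object$ncomp,
               ncomp_requested = object$ncomp_requested,
               eigvals = object$eigvals,
               x_center = object$x_center, x_scale = object$x_scale,
               y_center = object$y_center, y_scale = object$y_scale,
               settings = object$settings,
               variable_ids = object$variable_ids,
               response_ids = object$response_ids,
               sample_ids = object$sample_ids,
               warnings = object$meta$warnings)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a serialized PLS2 model
#'
#' @param dir directory written by [write_model()].
#' @return a \code{"pls2"} object sufficient for prediction and
#'   interpretation.
#' @export
read_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  rd <- function(nm) as.matrix(utils::read.csv(file.path(dir,
                                                         paste0(nm, ".csv"))))
  obj <- list(ncomp = meta$ncomp, ncomp_requested = meta$ncomp_requested,
              weights = unname(rd("W")), Wstar = unname(rd("Wstar")),
              x_loadings = unname(rd("P")), y_loadings = unname(rd("Q")),
              scores = unname(rd("T")), y_scores = unname(rd("U")),
              coefficients = unname(rd("B")),
              residuals = list(X = unname(rd("E")), Y = unname(rd("F"))),
              eigvals = meta$eigvals,
              x_center = meta$x_center, x_scale = meta$x_scale,
              y_center = meta$y_center, y_scale = meta$y_scale,
              settings = meta$settings,
              variable_ids = meta$variable_ids,
              response_ids = meta$response_ids,
              sample_ids = meta$sample_ids,
              meta = list(warnings = meta$warnings))
  class(obj) <- meta$class
  obj
}

#' Run a configured end-to-end workflow
#'
#' Executes a reproducible fit-validate-interpret pipeline from a YAML or
#' JSON configuration: read the input tables, pre-treat, fit (with a fixed
#' component count or automatic selection), post-transform, and write the
#' serialized model, interpretation tables and a machine-readable log of
#' seeds and parameters to the output directory.
#'
#' @param config path to a YAML/JSON file, or an equivalent named list with
#'   fields \code{x} (path or matrix), \code{y} (path, vector or matrix),
#'   optional \code{z} (constraints), \code{method} (pls2/ocpls2/kpls2),
#'   \code{ncomp} (integer or \code{"auto"}), \code{ncomp_max},
#'   \code{scale}, \code{y_transform}, \code{validation} (list with k,
#'   n_perm, alpha), \code{seed} and \code{outdir}.
#' @return invisible list with the fitted model, the validation report (when
#'   selection ran) and the output directory.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  req <- c("x", "y", "outdir")
  miss <- setdiff(req, names(config))
  if (length(miss) > 0)
    stop("config is missing field(s): ", paste(miss, collapse = ", "))
  X <- if (is.character(config$x)) read_data_matrix(config$x)
       else as.matrix(config$x)
  Y <- if (is.character(config$y)) read_data_matrix(config$y)
       else as.matrix(config$y)
  Z <- if (!is.null(config$z)) {
    if (is.character(config$z)) read_data_matrix(config$z)
    else as.matrix(config$z)
  }
  method <- config$method %||% "pls2"
  seed <- config$seed %||% 1L
  scale <- config$scale %||% "none"
  y_transform <- config$y_transform %||% "none"
  val <- config$validation %||% list()
  k <- val$k %||% 7; n_perm <- val$n_perm %||% 99
  alpha <- val$alpha %||% 0.05
  report <- NULL
  ncomp <- config$ncomp %||% "auto"
  if (identical(ncomp, "auto")) {
    report <- select_ncomp(X, Y, ncomp_max = config$ncomp_max %||% 5,
                           method = method, Z = Z, k = k, n_perm = n_perm,
                           alpha = alpha, seed = seed, scale = scale,
                           y_transform = y_transform)
    if (is.na(report$chosen_A))
      stop("component selection failed: no count passes the permutation test")
    ncomp <- report$chosen_A
  }
  fit <- switch(method,
    pls2 = pls2(X, Y, ncomp = ncomp, scale = scale,
                y_transform = y_transform),
    ocpls2 = ocpls2(X, Y, Z = Z, ncomp = ncomp, scale = scale,
                    y_transform = y_transform),
    kpls2 = kpls2(X, Y, kernel = do.call(kernel_spec,
                                         config$kernel %||% list()),
                  ncomp = ncomp, scale = scale, y_transform = y_transform),
    stop("unknown method: ", method))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(fit, "pls2")) {
    write_model(fit, file.path(config$outdir, "model"))
    v <- vip(fit)
    utils::write.csv(v, file.path(config$outdir, "vip.csv"),
                     row.names = FALSE)
  }
  log <- list(method = method, ncomp = ncomp, seed = seed, scale = scale,
              y_transform = y_transform,
              r2 = as.list(r_squared(fit)),
              validation = if (!is.null(report))
                list(chosen_A = report$chosen_A, status = report$status),
              r_version = as.character(getRversion()),
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, file.path(config$outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(fit = fit, report = report, outdir = config$outdir))
}
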