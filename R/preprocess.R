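#' Impute missing values in a data matrix
#'
#' Replaces missing entries column-wise, as commonly needed for MS-based
#' metabolomic tables where peaks below the limit of quantification are
#' reported as \code{NA}.
#'
#' @param X numeric matrix (samples in rows, variables in columns).
#' @param strategy \code{"half-minimum"} replaces missing entries with half of
#'   the smallest observed value of the column; \code{"column-median"} uses the
#'   column median of the observed entries.
#' @return list with \code{values} (complete matrix) and \code{mask} (logical
#'   matrix marking imputed cells).
#' @export
impute_missing <- function(X, strategy = c("half-minimum", "column-median")) {
  strategy <- match.arg(strategy)
  X <- as.matrix(X)
  mask <- is.na(X)
  bad <- colSums(!mask) == 0
  if (any(bad))
    stop("fully missing column(s): ", paste(colnames(X)[bad], collapse = ", "))
  for (j in which(colSums(mask) > 0)) {
    obs <- X[!mask[, j], j]
    fill <- if (strategy == "half-minimum") min(obs) / 2 else stats::median(obs)
    X[mask[, j], j] <- fill
  }
  list(values = X, mask = mask)
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution by dividing each row by the median quotient of
#' its entries against a reference spectrum. Zeros and missing values are
#' excluded from the quotient computation.
#'
#' @param X numeric matrix, strictly non-negative where quotients are taken.
#' @param reference reference spectrum (length-P vector); defaults to the
#'   column-wise median of \code{X}.
#' @return list with \code{values}, \code{factors} (per-sample dilution
#'   factors) and \code{reference}.
#' @export
pqn_normalize <- function(X, reference = NULL) {
  X <- as.matrix(X)
  if (is.null(reference)) reference <- apply(X, 2, stats::median, na.rm = TRUE)
  if (length(reference) != ncol(X))
    stop("reference length does not match the number of variables")
  factors <- vapply(seq_len(nrow(X)), function(i) {
    ok <- !is.na(X[i, ]) & X[i, ] != 0 & reference != 0
    if (!any(ok)) stop("sample ", i, " has no usable entries for PQN")
    stats::median(X[i, ok] / reference[ok])
  }, numeric(1))
  list(values = X / factors, factors = factors, reference = reference)
}

#' Column scaling and mean centring
#'
#' @param X numeric matrix.
#' @param mode \code{"uv"} (unit variance: divide by the column standard
#'   deviation), \code{"pareto"} (divide by its square root) or \code{"none"}.
#' @param center subtract column means first.
#' @return list with \code{values}, \code{center}, \code{scale} and
#'   \code{constant} (flag for constant columns, scaled by 1).
#' @export
scale_columns <- function(X, mode = c("none", "uv", "pareto"), center = TRUE) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  mu <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, mu, "-")
  s <- apply(X, 2, stats::sd)
  constant <- s < .Machine$double.eps^0.5
  fac <- switch(mode, none = rep(1, ncol(X)), uv = s, pareto = sqrt(s))
  fac[constant | fac == 0] <- 1
  list(values = sweep(Xc, 2, fac, "/"), center = mu, scale = fac,
       constant = constant, mode = mode)
}

#' Response transformation with an exact inverse
#'
#' Square-root or log transforms used to linearise the relationship between
#' scores and a quantitative response. The inverse is applied by
#' \code{predict} methods and error metrics so that results are reported in
#' original response units.
#'
#' @param y numeric vector or matrix.
#' @param transform one of \code{"none"}, \code{"sqrt"}, \code{"log"}.
#' @return list with \code{values} and \code{transform}.
#' @export
transform_response <- function(y, transform = c("none", "sqrt", "log")) {
  transform <- match.arg(transform)
  v <- apply_transform(y, transform)
  list(values = v, transform = transform)
}

apply_transform <- function(y, transform) {
  switch(transform,
    none = y,
    sqrt = {
      if (any(y < 0, na.rm = TRUE))
        stop("sqrt transform: negative values in samples ",
             paste(which(rowSums(as.matrix(y) < 0) > 0), collapse = ", "))
      sqrt(y)
    },
    log = {
      if (any(y <= 0, na.rm = TRUE))
        stop("log transform: non-positive values in samples ",
             paste(which(rowSums(as.matrix(y) <= 0) > 0), collapse = ", "))
      log(y)
    })
}

invert_transform <- function(y, transform) {
  switch(transform, none = y, sqrt = y^2, log = exp(y))
}

#' Fit a pre-treatment recipe
#'
#' Applies, in order: missing-value imputation, PQN normalization, a
#' variable-wise transform, then scaling and centring, recording every fitted
#' parameter so the same treatment can be replayed on new samples with
#' training-set parameters only.
#'
#' @param X numeric matrix (samples x variables).
#' @param impute \code{NULL} (none) or an imputation strategy, see
#'   [impute_missing()].
#' @param pqn apply probabilistic quotient normalization.
#' @param transform variable-wise transform (\code{"none"}, \code{"sqrt"},
#'   \code{"log"}) applied before scaling.
#' @param scale column scaling mode, see [scale_columns()].
#' @param center mean-centre columns.
#' @return object of class \code{"pretreat"} with the treated matrix in
#'   \code{$values}; use \code{predict()} to replay on new data.
#' @export
pre_treat <- function(X, impute = NULL, pqn = FALSE,
                      transform = c("none", "sqrt", "log"),
                      scale = c("none", "uv", "pareto"), center = TRUE) {
  transform <- match.arg(transform)
  scale <- match.arg(scale)
  X <- as.matrix(X)
  out <- list(impute = impute, pqn = pqn, transform = transform)
  if (!is.null(impute)) X <- impute_missing(X, impute)$values
  if (pqn) {
    p <- pqn_normalize(X)
    X <- p$values
    out$reference <- p$reference
    out$factors <- p$factors
  }
  X <- apply_transform(X, transform)
  sc <- scale_columns(X, scale, center)
  out$center <- sc$center
  out$scale <- sc$scale
  out$scale_mode <- scale
  out$centered <- center
  out$values <- sc$values
  class(out) <- "pretreat"
  out
}

#' Replay a fitted pre-treatment recipe on new samples
#'
#' @param object a \code{"pretreat"} recipe.
#' @param newdata matrix with the same variables as the training data.
#' @param ... unused.
#' @return treated matrix on the training scale.
#' @export
predict.pretreat <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (length(object$center) != ncol(X))
    stop("newdata has ", ncol(X), " columns; recipe was fitted on ",
         length(object$center))
  if (!is.null(object$impute)) X <- impute_missing(X, object$impute)$values
  if (object$pqn) X <- pqn_normalize(X, object$reference)$values
  X <- apply_transform(X, object$transform)
  sweep(sweep(X, 2, object$center, "-"), 2, object$scale, "/")
}
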