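#' Kernel specification
#'
#' @param family \code{"linear"}, \code{"polynomial"} or \code{"rbf"}.
#' @param degree polynomial degree (>= 1).
#' @param offset polynomial offset c in \eqn{(x^t y + c)^d}.
#' @param gamma RBF width in \eqn{\exp(-\gamma \|x - y\|^2)}; defaults to
#'   \code{1/P} at fit time when \code{NULL}.
#' @return object of class \code{"kernel_spec"}.
#' @export
kernel_spec <- function(family = c("linear", "polynomial", "rbf"),
                        degree = 2, offset = 1, gamma = NULL) {
  family <- match.arg(family)
  if (family == "polynomial" && (degree < 1 || degree != round(degree)))
    stop("polynomial degree must be a positive integer")
  if (family == "rbf" && !is.null(gamma) && gamma <= 0)
    stop("rbf gamma must be positive")
  structure(list(family = family, degree = degree, offset = offset,
                 gamma = gamma), class = "kernel_spec")
}

#' Gram matrix between two sample sets
#'
#' Entry (i, j) is the kernel evaluation between row i of \code{X1} and row j
#' of \code{X2}; for \code{X1 = X2} the result is symmetric positive
#' semi-definite.
#'
#' @param X1,X2 matrices with equal column counts.
#' @param spec a [kernel_spec()].
#' @return \code{nrow(X1)} x \code{nrow(X2)} kernel matrix.
#' @export
gram_matrix <- function(X1, X2, spec) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2)) stop("X1 and X2 must have equal column counts")
  switch(spec$family,
    linear = tcrossprod(X1, X2),
    polynomial = (tcrossprod(X1, X2) + spec$offset)^spec$degree,
    rbf = {
      g <- if (is.null(spec$gamma)) 1 / ncol(X1) else spec$gamma
      d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
      exp(-g * pmax(d2, 0))
    })
}

#' Fit a kernel PLS2 model (KPLS2)
#'
#' PLS2 regression performed in the feature space induced by a kernel
#' function, for moderate or strong non-linearity. The training Gram matrix is
#' double-centred and score extraction runs in the dual: at each step the
#' score is the image under the residual kernel of the dominant direction of
#' \eqn{F^t K F}, which reproduces the primal eigenvalue step when the kernel
#' is linear. The model stores the dual regression coefficients and the
#' training centring statistics needed for leakage-free prediction.
#'
#' @inheritParams pls2
#' @param kernel a [kernel_spec()].
#' @return object of class \code{"kpls2"}.
#' @export
kpls2 <- function(X, Y, kernel = kernel_spec("linear"), ncomp,
                  center = TRUE, scale = c("none", "uv", "pareto"),
                  y_scale = c("none", "uv", "pareto"),
                  y_transform = c("none", "sqrt", "log")) {
  scale <- match.arg(scale); y_scale <- match.arg(y_scale)
  y_transform <- match.arg(y_transform)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  N <- nrow(X)
  amax <- N - 1L
  if (ncomp < 1) stop("ncomp must be at least 1")
  if (ncomp > amax) {
    warning("ncomp reduced to the maximum extractable ", amax)
    ncomp <- amax
  }
  if (is.null(kernel$gamma) && kernel$family == "rbf")
    kernel$gamma <- 1 / ncol(X)
  Yt <- apply_transform(Y, y_transform)
  scx <- scale_columns(X, scale, center)
  scy <- scale_columns(Yt, y_scale, center)
  Xt <- scx$values; Yc <- scy$values
  K0 <- gram_matrix(Xt, Xt, kernel)
  km <- colMeans(K0); kmm <- mean(K0)
  Kc <- K0 - matrix(km, N, N, byrow = TRUE) - matrix(km, N, N) + kmm

  EK <- Kc; Fr <- Yc
  D <- diag(N)                      # accumulated deflation operator
  Tm <- matrix(0, N, ncomp); Dual <- matrix(0, N, ncomp)
  eig <- numeric(ncomp)
  tol_ref <- sum((Kc %*% Yc) * Yc)  # trace(Y' Kc Y) scale reference
  a <- 0L; truncated <- FALSE
  for (i in seq_len(ncomp)) {
    Cm <- crossprod(Fr, EK %*% Fr)  # M x M, eigenvalues = squared sing. vals
    es <- eigen((Cm + t(Cm)) / 2, symmetric = TRUE)
    sigma2 <- es$values[1]
    if (sigma2 <= 1e-12 * max(tol_ref, .Machine$double.eps)) {
      truncated <- TRUE; break
    }
    v1 <- es$vectors[, 1]
    sigma <- sqrt(sigma2)
    t_i <- drop(EK %*% (Fr %*% v1)) / sigma
    tt <- sum(t_i^2)
    if (tt <= .Machine$double.eps * N) { truncated <- TRUE; break }
    a <- i
    Tm[, i] <- t_i
    Dual[, i] <- drop(crossprod(D, Fr %*% v1)) / sigma
    eig[i] <- sigma2
    Pi <- diag(N) - tcrossprod(t_i) / tt
    D <- Pi %*% D
    EK <- Pi %*% EK %*% Pi
    Fr <- Fr - tcrossprod(t_i, drop(crossprod(Fr, t_i))) / tt
  }
  if (a == 0L) stop("no component could be extracted in the feature space")
  keep <- seq_len(a)
  Tm <- Tm[, keep, drop = FALSE]; Dual <- Dual[, keep, drop = FALSE]
  tt <- colSums(Tm^2)
  Q <- sweep(crossprod(Yc, Tm), 2, tt, "/")
  PtW <- sweep(crossprod(Tm, Kc %*% Dual), 1, tt, "/")
  R_dual <- Dual %*% solve(PtW, t(Q))     # N x M dual coefficients
  fitted_c <- Kc %*% R_dual
  warn <- if (truncated)
    paste0("covariance exhausted: model truncated to ", a, " component(s)")
  if (!is.null(warn)) warning(warn)
  structure(list(
    ncomp = a, ncomp_requested = ncomp, kernel = kernel,
    scores = Tm, y_loadings = Q, dual_coef = R_dual, eigvals = eig[keep],
    residuals = list(Y = Yc - tcrossprod(Tm, Q)),
    x_train = Xt, km = km, kmm = kmm,
    x_center = scx$center, x_scale = scx$scale,
    y_center = scy$center, y_scale = scy$scale,
    y = Yc, X_raw = X, Y_raw = Y,
    settings = list(center = center, scale = scale, y_scale = y_scale,
                    y_transform = y_transform),
    response_ids = colnames(Yt) %||% paste0("Y", seq_len(ncol(Yt))),
    meta = list(warnings = warn),
    call = match.call()), class = "kpls2")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kpls2 <- function(x, ...) {
  cat("Kernel PLS2 model (", x$kernel$family, " kernel): ",
      x$ncomp, " latent variable(s)\n", sep = "")
  r2 <- r_squared(x)
  cat("R2 per response:", paste(sprintf("%s = %.3f", names(r2), r2),
                                collapse = ", "), "\n")
  if (x$ncomp >= nrow(x$scores) - 1)
    cat("note: component count equals its maximum; training residuals may\n",
        "interpolate the data (overfit)\n")
  invisible(x)
}

#' Predict from a kernel PLS2 model
#'
#' The test kernel against the training rows is centred with training
#' statistics only (no test-set leakage), multiplied by the dual coefficients
#' and back-transformed to original response units.
#'
#' @param object a \code{"kpls2"} model.
#' @param newdata matrix of new samples; defaults to the training X.
#' @param type as in [predict.pls2()] (\code{"scores"} unavailable).
#' @param ... unused.
#' @export
predict.kpls2 <- function(object, newdata = NULL,
                          type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$X_raw
  Xn <- pretreat_x(object, newdata)
  Kt0 <- gram_matrix(Xn, object$x_train, object$kernel)
  Ktc <- Kt0 - matrix(object$km, nrow(Kt0), ncol(Kt0), byrow = TRUE) -
    rowMeans(Kt0) + object$kmm
  Yc_hat <- Ktc %*% object$dual_coef
  if (type == "link") {
    colnames(Yc_hat) <- object$response_ids
    return(Yc_hat)
  }
  backtransform_y(object, Yc_hat)
}

#' @export
fitted.kpls2 <- function(object, ...) predict(object)

#' @export
residuals.kpls2 <- function(object, ...) object$residuals$Y

#' @export
refit.kpls2 <- function(object, rows, y = NULL, ...) {
  Y <- if (is.null(y)) object$Y_raw else as.matrix(y)
  s <- object$settings
  suppressWarnings(
    kpls2(object$X_raw[rows, , drop = FALSE], Y[rows, , drop = FALSE],
          kernel = object$kernel, ncomp = object$ncomp_requested,
          center = s$center, scale = s$scale, y_scale = s$y_scale,
          y_transform = s$y_transform))
}
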