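#' Dummy-code a constraint table
#'
#' Builds the N x L constraint matrix Z from a data frame: numeric columns are
#' kept as quantitative covariates, factor/character columns are expanded into
#' raw 0/1 dummy columns (one per level beyond the first, or all levels with
#' \code{full = TRUE}). Dummies are not centred by default, matching the
#' common practice of coding a two-level nuisance factor as 0/1; centred
#' coding is available for unbalanced designs.
#'
#' @param data data frame (or matrix) of constraint columns.
#' @param centre centre the coded columns.
#' @param full keep a dummy column for every factor level.
#' @return numeric constraint matrix.
#' @export
constraint_matrix <- function(data, centre = FALSE, full = FALSE) {
  data <- as.data.frame(data)
  cols <- lapply(names(data), function(nm) {
    v <- data[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      m <- stats::model.matrix(~ f - 1)
      colnames(m) <- paste(nm, levels(f), sep = ".")
      if (!full && ncol(m) > 1) m <- m[, -1, drop = FALSE]
    }
    m
  })
  Z <- do.call(cbind, cols)
  if (centre) Z <- scale(Z, center = TRUE, scale = FALSE)
  Z
}

check_constraints <- function(Z, N) {
  Z <- as.matrix(Z)
  if (nrow(Z) != N) stop("constraint matrix has ", nrow(Z),
                         " rows but the X-block has ", N)
  if (any(colSums(abs(Z)) == 0)) stop("all-zero constraint column")
  Z
}

#' Constrained dominant covariance weight
#'
#' Weight extraction for orthogonally-constrained PLS2: the covariance
#' operator is projected onto the orthogonal complement of the column space of
#' \eqn{V_i}, the right singular vectors of \eqn{Z^t E_{i-1}} with non-zero
#' singular values, so that the resulting score \eqn{t = E w} satisfies
#' \eqn{Z^t t = 0}.
#'
#' @param E,F residual matrices.
#' @param Z constraint matrix (N x L).
#' @param tol_ref degeneracy reference as in [compute_weight()].
#' @param rank_tol relative singular-value cutoff for the rank of
#'   \eqn{Z^t E}.
#' @return list with unit vector \code{w} and eigenvalue \code{lambda}.
#' @export
constrained_weight <- function(E, F, Z, tol_ref = NULL, rank_tol = 1e-10) {
  Z <- check_constraints(Z, nrow(E))
  ze <- crossprod(Z, E)                      # L x P
  sv <- svd(ze, nu = 0)
  # relative cutoff, floored at round-off scale so an inactive constraint
  # (Z'E = 0 up to noise) selects no direction at all
  floor_tol <- .Machine$double.eps * max(dim(ze)) *
    sqrt(sum(Z^2) * sum(E^2))
  r <- sum(sv$d > max(rank_tol * sv$d[1], floor_tol))
  cross <- crossprod(E, F)
  if (is.null(tol_ref)) tol_ref <- sum(cross^2)
  if (r > 0) {
    V <- sv$v[, seq_len(r), drop = FALSE]    # P x r
    cross <- cross - V %*% crossprod(V, cross)
  }
  s1 <- svd(cross, nu = 1, nv = 0)
  lambda <- s1$d[1]^2
  if (lambda <= 1e-12 * tol_ref)
    stop("no admissible constrained direction remains")
  list(w = fix_sign(s1$u[, 1]), lambda = lambda)
}

#' Fit an orthogonally-constrained PLS2 model (oCPLS2)
#'
#' PLS2 whose scores are forced to be orthogonal to a constraint matrix
#' \code{Z} coding nuisance design factors (e.g. a paired sampling factor):
#' each weight is the dominant eigenvector of the covariance operator
#' projected onto the complement of the constraint-relevant directions
#' (recomputed at every deflation step), so \eqn{Z^t T = 0} and the model
#' focuses on the response while ignoring variation aligned with the coded
#' factors. Post-transformation applies unchanged to the result.
#'
#' @inheritParams pls2
#' @param Z constraint matrix or data frame (auto dummy-coded via
#'   [constraint_matrix()]).
#' @return object of class \code{c("ocpls2", "pls2")} carrying \code{$Z}.
#' @export
ocpls2 <- function(X, Y, Z, ncomp, center = TRUE,
                   scale = c("none", "uv", "pareto"),
                   y_scale = c("none", "uv", "pareto"),
                   y_transform = c("none", "sqrt", "log")) {
  scale <- match.arg(scale); y_scale <- match.arg(y_scale)
  y_transform <- match.arg(y_transform)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.data.frame(Z)) Z <- constraint_matrix(Z)
  Z <- check_constraints(Z, nrow(X))
  settings <- list(center = center, scale = scale, y_scale = y_scale,
                   y_transform = y_transform)
  builder <- function(Xc, Yc, tol_ref) {
    function(E, F) {
      tryCatch(constrained_weight(E, F, Z, tol_ref = tol_ref),
               error = function(e) signal_degenerate(conditionMessage(e)))
    }
  }
  obj <- pls2_engine(X, Y, ncomp, settings, weight_builder = builder,
                     extra = list(Z = Z), cls = c("ocpls2", "pls2"))
  obj$call <- match.call()
  obj
}

#' @export
print.ocpls2 <- function(x, ...) {
  cat("Orthogonally-constrained ")
  NextMethod()
  cat("max |Z' T| =", format(max(abs(crossprod(x$Z, x$scores))), digits = 3),
      "\n")
  invisible(x)
}

#' @export
refit.ocpls2 <- function(object, rows, y = NULL, ...) {
  Y <- if (is.null(y)) object$Y_raw else as.matrix(y)
  s <- object$settings
  suppressWarnings(
    ocpls2(object$X_raw[rows, , drop = FALSE], Y[rows, , drop = FALSE],
           Z = object$Z[rows, , drop = FALSE],
           ncomp = object$ncomp_requested, center = s$center,
           scale = s$scale, y_scale = s$y_scale,
           y_transform = s$y_transform))
}
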