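#' Re-run the deflation algorithm with transformed weights
#'
#' For any non-singular matrix \code{H}, running the iterative deflation loop
#' with the columns of \eqn{\tilde W = W H} as weights leaves the residuals of
#' both blocks and the regression coefficients unchanged, while the score
#' structure changes. This invariance is the basis of the post-transformation
#' procedure.
#'
#' @param object fitted \code{"pls2"} model.
#' @param H non-singular A x A matrix (condition number below 1e12).
#' @return a \code{"pls2"} object with the new scores, loadings, weights and
#'   recomputed coefficients/residuals; field \code{$H} records the transform.
#' @export
transform_weights <- function(object, H) {
  H <- as.matrix(H)
  A <- object$ncomp
  if (!all(dim(H) == c(A, A))) stop("H must be ", A, " x ", A)
  d <- svd(H, nu = 0, nv = 0)$d
  if (d[length(d)] <= 0 || d[1] / d[length(d)] > 1e12)
    stop("H is singular or numerically singular")
  Wt <- object$weights %*% H
  dec <- deflate_with_weights(object$x, object$y, Wt)
  new <- object
  new$weights <- Wt
  new$scores <- dec$T; new$x_loadings <- dec$P; new$y_loadings <- dec$Q
  new$Wstar <- dec$Wstar; new$coefficients <- dec$B
  new$residuals <- list(X = dec$E, Y = dec$F)
  new$y_scores <- dec$U; new$y_weights <- dec$C
  new$eigvals <- rep(NA_real_, A)
  new$H <- H
  new
}

# deflation loop with a prescribed weight sequence (columns of Wt)
deflate_with_weights <- function(Xc, Yc, Wt) {
  N <- nrow(Xc); A <- ncol(Wt); M <- ncol(Yc)
  E <- Xc; Fr <- Yc
  Tm <- matrix(0, N, A); U <- matrix(0, N, A); C <- matrix(0, M, A)
  for (i in seq_len(A)) {
    t_i <- drop(E %*% Wt[, i])
    tt <- sum(t_i^2)
    if (tt <= .Machine$double.eps * N)
      stop("transformed weight ", i, " produces a null score")
    c_i <- drop(crossprod(Fr, t_i))
    cn <- sqrt(sum(c_i^2)); if (cn > 0) c_i <- c_i / cn
    Tm[, i] <- t_i; C[, i] <- c_i; U[, i] <- drop(Fr %*% c_i)
    E <- E - tcrossprod(t_i, drop(crossprod(E, t_i))) / tt
    Fr <- Fr - tcrossprod(t_i, drop(crossprod(Fr, t_i))) / tt
  }
  tt <- colSums(Tm^2)
  Pl <- sweep(crossprod(Xc, Tm), 2, tt, "/")
  Q <- sweep(crossprod(Yc, Tm), 2, tt, "/")
  Wstar <- Wt %*% solve(crossprod(Pl, Wt))
  list(T = Tm, P = Pl, Q = Q, U = U, C = C, Wstar = Wstar,
       B = Wstar %*% t(Q), E = E, F = Fr)
}

#' Post-transformation of a PLS2 model (ptPLS2)
#'
#' Splits the latent space of a fitted PLS2 model into a predictive subspace
#' (scores correlated with the response) and an orthogonal subspace (scores
#' with \eqn{Y^t T_o = 0}) without changing the regression coefficients or the
#' residuals of either block:
#' \deqn{X = T_p P_p^t + T_o P_o^t + E, \qquad Y = T_p Q_p^t + F.}
#'
#' The orthogonal rotation \code{G} is built from the singular value
#' decomposition of \eqn{W^t X^t Y}: weight directions with non-zero singular
#' values span the predictive subspace (its dimension \eqn{A_p} is the
#' numerical rank, relative cutoff 1e-10), while null-space directions yield
#' scores orthogonal to the response. Orthogonal components are extracted
#' first when the deflation loop is re-run, so the predictive scores are
#' cleaned of structured noise; any orthonormal ordering is admissible by the
#' invariance of residuals and coefficients, and this one reproduces the
#' OPLS-equivalent behaviour for a single response.
#'
#' @param object fitted \code{"pls2"} (or constrained) model with A >= 1.
#' @param rank_tol relative singular-value cutoff for the predictive rank.
#' @return object of class \code{"ptpls2"} with fields \code{Tp, Pp, Qp, To,
#'   Po, Ap, Ao, G, Wtilde}, the full transformed decomposition, and the
#'   parent model in \code{$parent}.
#' @seealso [predictive_vip()], [selectivity_ratio()]
#' @export
post_transform <- function(object, rank_tol = 1e-10) {
  A <- object$ncomp
  if (A < 1) stop("model has no latent variables")
  cross <- crossprod(object$weights, crossprod(object$x, object$y))  # A x M
  sv <- svd(cross, nu = A, nv = 0)
  d <- sv$d
  Ap <- sum(d > rank_tol * max(d, .Machine$double.eps))
  Ap <- max(Ap, 1L)
  Ao <- A - Ap
  # orthogonal (null-space) directions first, predictive last; with no
  # orthogonal block there is nothing to separate and the model is kept as is
  G <- if (Ao == 0) diag(A) else
    cbind(sv$u[, Ap + seq_len(Ao), drop = FALSE],
          sv$u[, seq_len(Ap), drop = FALSE])
  new <- transform_weights(object, G)
  io <- seq_len(Ao); ip <- Ao + seq_len(Ap)
  out <- list(parent = object, G = G, Wtilde = new$weights,
              Ap = Ap, Ao = Ao,
              Tp = new$scores[, ip, drop = FALSE],
              Pp = new$x_loadings[, ip, drop = FALSE],
              Qp = new$y_loadings[, ip, drop = FALSE],
              To = new$scores[, io, drop = FALSE],
              Po = new$x_loadings[, io, drop = FALSE],
              model = new)
  class(out) <- "ptpls2"
  out
}

#' @export
print.ptpls2 <- function(x, ...) {
  cat("Post-transformed PLS2 model:", x$Ap, "predictive +", x$Ao,
      "orthogonal latent variable(s)\n")
  r2 <- r_squared(x$model)
  cat("R2 per response:", paste(sprintf("%s = %.3f", names(r2), r2),
                                collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.ptpls2 <- function(object, newdata = NULL, ...) {
  predict(object$model, newdata = newdata, ...)
}

#' @export
coef.ptpls2 <- function(object, ...) coef(object$model)

#' VIP scores split into predictive and orthogonal parts
#'
#' The variable-influence-on-projection score restricted to the predictive
#' components of a post-transformed model (weighted by the explained Y-block
#' sum of squares, \code{vip_p}) and to the orthogonal components (weighted by
#' the explained X-block sum of squares, \code{vip_o}, since orthogonal
#' components explain no Y-variance by construction). Each score vector has
#' mean square one. Variables whose main role is to model structured noise
#' show high \code{vip_o} and low \code{vip_p} while their overall VIP can
#' still be large.
#'
#' @param pt a \code{"ptpls2"} model.
#' @return data frame with \code{variable}, \code{vip_p} and \code{vip_o}
#'   (all zero, with attribute \code{no_orthogonal = TRUE}, when Ao = 0).
#' @export
predictive_vip <- function(pt) {
  if (!inherits(pt, "ptpls2")) stop("pt must be a post-transformed model")
  P <- nrow(pt$Wtilde)
  Wn <- pt$Wtilde
  # G is orthogonal so columns are orthonormal already; normalize defensively
  Wn <- sweep(Wn, 2, sqrt(colSums(Wn^2)), "/")
  io <- seq_len(pt$Ao); ip <- pt$Ao + seq_len(pt$Ap)
  tt <- colSums(pt$model$scores^2)
  ssy <- tt * colSums(pt$model$y_loadings^2)
  ssx <- tt * colSums(pt$model$x_loadings^2)
  vip_p <- sqrt(P * (Wn[, ip, drop = FALSE]^2 %*% ssy[ip]) / sum(ssy[ip]))
  if (pt$Ao > 0) {
    vip_o <- sqrt(P * (Wn[, io, drop = FALSE]^2 %*% ssx[io]) / sum(ssx[io]))
    no_orth <- FALSE
  } else {
    vip_o <- rep(0, P)
    no_orth <- TRUE
  }
  out <- data.frame(variable = pt$parent$variable_ids,
                    vip_p = drop(vip_p), vip_o = drop(vip_o))
  attr(out, "no_orthogonal") <- no_orth
  out
}
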