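#' Dominant covariance weight vector
#'
#' Solves the eigenvalue problem at the heart of the PLS2 algorithm: the
#' returned unit vector \eqn{w} is the dominant eigenvector of
#' \eqn{E^t F F^t E} with eigenvalue \eqn{\lambda}. It is computed from the
#' singular value decomposition of the cross-product \eqn{E^t F} (P x M),
#' which is mathematically identical but numerically stabler and cheaper than
#' forming the P x P operator for wide matrices. The sign is fixed so that the
#' largest-magnitude entry of \eqn{w} is positive.
#'
#' @param E,F residual matrices of the X- and Y-block with equal row counts.
#' @param tol_ref reference squared norm for the degeneracy test; \eqn{\lambda}
#'   below \code{1e-12 * tol_ref} signals that no covariance remains. Defaults
#'   to the squared Frobenius norm of \eqn{E^t F}.
#' @return list with unit vector \code{w} and eigenvalue \code{lambda}.
#' @export
compute_weight <- function(E, F, tol_ref = NULL) {
  if (nrow(E) != nrow(F)) stop("E and F must have equal row counts")
  cross <- crossprod(E, F)
  if (is.null(tol_ref)) tol_ref <- sum(cross^2)
  sv <- svd(cross, nu = 1, nv = 0)
  lambda <- sv$d[1]^2
  if (lambda <= 1e-12 * tol_ref)
    stop("no remaining covariance between the blocks")
  w <- fix_sign(sv$u[, 1])
  list(w = w, lambda = lambda)
}

fix_sign <- function(w) {
  i <- which.max(abs(w))
  if (w[i] < 0) -w else w
}

# Shared iterative deflation loop. `weight_fun(E, F)` returns list(w, lambda)
# or signals a condition with class "latentpls_degenerate"; the loop then
# truncates. Returns the full decomposition on the treated scale.
deflate_loop <- function(Xc, Yc, ncomp, weight_fun) {
  N <- nrow(Xc); P <- ncol(Xc); M <- ncol(Yc)
  E <- Xc; Fr <- Yc
  W <- matrix(0, P, ncomp); Tm <- matrix(0, N, ncomp)
  U <- matrix(0, N, ncomp); C <- matrix(0, M, ncomp)
  eig <- numeric(ncomp)
  a <- 0L
  truncated <- FALSE
  for (i in seq_len(ncomp)) {
    res <- tryCatch(weight_fun(E, Fr), latentpls_degenerate = function(e) NULL)
    if (is.null(res)) { truncated <- TRUE; break }
    t_i <- drop(E %*% res$w)
    tt <- sum(t_i^2)
    if (tt <= .Machine$double.eps * N) { truncated <- TRUE; break }
    c_i <- drop(crossprod(Fr, t_i))
    cn <- sqrt(sum(c_i^2))
    if (cn > 0) c_i <- c_i / cn
    a <- i
    W[, i] <- res$w; Tm[, i] <- t_i
    C[, i] <- c_i; U[, i] <- drop(Fr %*% c_i)
    eig[i] <- res$lambda
    E <- E - tcrossprod(t_i, drop(crossprod(E, t_i))) / tt
    Fr <- Fr - tcrossprod(t_i, drop(crossprod(Fr, t_i))) / tt
  }
  if (a == 0L) stop("no component could be extracted: ",
                    "the blocks share no covariance")
  keep <- seq_len(a)
  Tm <- Tm[, keep, drop = FALSE]; W <- W[, keep, drop = FALSE]
  tt <- colSums(Tm^2)
  Pl <- sweep(crossprod(Xc, Tm), 2, tt, "/")
  Q <- sweep(crossprod(Yc, Tm), 2, tt, "/")
  PtW <- crossprod(Pl, W)
  Wstar <- W %*% solve(PtW)
  list(ncomp = a, truncated = truncated, W = W, T = Tm,
       U = U[, keep, drop = FALSE], C = C[, keep, drop = FALSE],
       eigvals = eig[keep], P = Pl, Q = Q, PtW = PtW, Wstar = Wstar,
       B = Wstar %*% t(Q), E = E, F = Fr)
}

check_centred <- function(X, block) {
  mu <- colMeans(X)
  ref <- max(apply(X, 2, stats::sd), .Machine$double.eps)
  if (max(abs(mu)) > 1e-8 * max(ref, 1))
    stop(block, "-block is not mean-centred; fit with center = TRUE ",
         "or centre it beforehand")
}

signal_degenerate <- function(msg) {
  cond <- structure(class = c("latentpls_degenerate", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

#' Fit a PLS2 regression model
#'
#' Projection to latent structures regression of a multivariate response
#' \code{Y} on predictors \code{X} by the eigenvalue algorithm with iterative
#' deflation: at each step the weight vector solves
#' \eqn{E_{i-1}^t F_{i-1} F_{i-1}^t E_{i-1} w_i = \lambda_i w_i}, the score is
#' \eqn{t_i = E_{i-1} w_i}, and both residual blocks are deflated by the
#' projector onto the orthogonal complement of \eqn{t_i}. The decomposition
#' satisfies \eqn{X = T P^t + E_A}, \eqn{Y = T Q^t + F_A}, \eqn{T = X W^*}
#' with \eqn{W^* = W (P^t W)^{-1}} and regression coefficients
#' \eqn{B = W^* Q^t}.
#'
#' Centring and scaling are estimated on the training data and stored with the
#' model; \code{predict()} replays them on new samples and back-transforms
#' predictions to the original response units.
#'
#' @param X numeric matrix of predictors (N x P), samples in rows.
#' @param Y numeric matrix or vector of responses (N x M).
#' @param ncomp number of latent variables; capped at \code{min(N - 1, P)}.
#'   If the remaining covariance degenerates earlier, the model is truncated
#'   with a warning recorded in \code{$meta}.
#' @param center mean-centre both blocks (if \code{FALSE}, the inputs must
#'   already be centred).
#' @param scale column scaling of the X-block: \code{"none"}, \code{"uv"} or
#'   \code{"pareto"}.
#' @param y_scale column scaling of the Y-block.
#' @param y_transform response transform (\code{"none"}, \code{"sqrt"},
#'   \code{"log"}) applied before centring; inverted by \code{predict()}.
#' @return an object of class \code{"pls2"}; see Details for components.
#'
#' @details The returned object contains \code{weights} (W), \code{Wstar},
#' \code{x_loadings} (P), \code{y_loadings} (Q), \code{scores} (T),
#' \code{y_scores} (U), \code{y_weights} (C, unit norm), \code{eigvals},
#' \code{coefficients} (B, on the treated scale), the residual matrices of
#' both blocks, the treated training matrices \code{x}/\code{y}, and the
#' pre-treatment parameters of both blocks.
#' @seealso [predict.pls2()], [explained_variance()], [vip()],
#'   [post_transform()], [ocpls2()], [kpls2()]
#' @examples
#' d <- sim_latent_data(N = 30, P = 20, seed = 1)
#' m <- pls2(d$X, d$Y, ncomp = 2)
#' summary(m)
#' @export
pls2 <- function(X, Y, ncomp, center = TRUE,
                 scale = c("none", "uv", "pareto"),
                 y_scale = c("none", "uv", "pareto"),
                 y_transform = c("none", "sqrt", "log")) {
  scale <- match.arg(scale); y_scale <- match.arg(y_scale)
  y_transform <- match.arg(y_transform)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (anyNA(X) || anyNA(Y))
    stop("missing values present; impute before fitting")
  settings <- list(center = center, scale = scale, y_scale = y_scale,
                   y_transform = y_transform)
  obj <- pls2_engine(X, Y, ncomp, settings, weight_builder = NULL)
  obj$call <- match.call()
  obj
}

# Common fitting path for pls2 and ocpls2. `weight_builder(Xc, Yc)` may return
# a closure(E, F) -> list(w, lambda); NULL gives the unconstrained weight.
pls2_engine <- function(X, Y, ncomp, settings, weight_builder = NULL,
                        extra = list(), cls = "pls2") {
  N <- nrow(X); P <- ncol(X)
  amax <- min(N - 1L, P)
  if (ncomp < 1) stop("ncomp must be at least 1")
  if (ncomp > amax) {
    warning("ncomp reduced to the maximum extractable ", amax)
    ncomp <- amax
  }
  Yt <- apply_transform(Y, settings$y_transform)
  if (settings$center) {
    scx <- scale_columns(X, settings$scale, center = TRUE)
    scy <- scale_columns(Yt, settings$y_scale, center = TRUE)
  } else {
    check_centred(X, "X"); check_centred(Yt, "Y")
    scx <- scale_columns(X, settings$scale, center = FALSE)
    scy <- scale_columns(Yt, settings$y_scale, center = FALSE)
  }
  Xc <- scx$values; Yc <- scy$values
  tol_ref <- sum(crossprod(Xc, Yc)^2)
  wf <- if (is.null(weight_builder)) {
    function(E, F) {
      tryCatch(compute_weight(E, F, tol_ref = tol_ref),
               error = function(e) signal_degenerate(conditionMessage(e)))
    }
  } else weight_builder(Xc, Yc, tol_ref)
  dec <- deflate_loop(Xc, Yc, ncomp, wf)
  warn <- NULL
  if (dec$truncated) {
    warn <- paste0("covariance exhausted: model truncated to ",
                   dec$ncomp, " component(s)")
    warning(warn)
  }
  vn <- colnames(X); if (is.null(vn)) vn <- paste0("V", seq_len(P))
  rn <- colnames(Yt); if (is.null(rn)) rn <- paste0("Y", seq_len(ncol(Yt)))
  sn <- rownames(X); if (is.null(sn)) sn <- as.character(seq_len(N))
  structure(c(list(
    ncomp = dec$ncomp, ncomp_requested = ncomp,
    weights = dec$W, Wstar = dec$Wstar,
    x_loadings = dec$P, y_loadings = dec$Q,
    scores = dec$T, y_scores = dec$U, y_weights = dec$C,
    eigvals = dec$eigvals, coefficients = dec$Wstar %*% t(dec$Q),
    residuals = list(X = dec$E, Y = dec$F),
    x = Xc, y = Yc, X_raw = X, Y_raw = Y,
    x_center = scx$center, x_scale = scx$scale,
    y_center = scy$center, y_scale = scy$scale,
    settings = settings,
    variable_ids = vn, response_ids = rn, sample_ids = sn,
    meta = list(warnings = warn)), extra),
    class = cls)
}

#' @export
print.pls2 <- function(x, ...) {
  cat("PLS2 model:", length(x$variable_ids), "predictors,",
      length(x$response_ids), "response(s),", x$ncomp, "latent variable(s)\n")
  r2 <- r_squared(x)
  cat("R2 per response:", paste(sprintf("%s = %.3f", names(r2), r2),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Coefficient of determination of a fitted model
#'
#' R2 per response on the modelled (treated) scale.
#' @param object fitted model.
#' @return named numeric vector.
#' @export
r_squared <- function(object) {
  ss <- colSums(object$y^2)
  r2 <- 1 - colSums(object$residuals$Y^2) / ss
  names(r2) <- object$response_ids
  r2
}

#' @export
summary.pls2 <- function(object, ...) {
  ev <- explained_variance(object)
  out <- list(model = object, r2 = r_squared(object), explained = ev)
  class(out) <- "summary.pls2"
  out
}

#' @export
print.summary.pls2 <- function(x, ...) {
  print(x$model)
  cat("\nExplained variance (fraction of block sum of squares):\n")
  print(round(x$explained$table, 4))
  invisible(x)
}

#' @export
coef.pls2 <- function(object, ...) {
  b <- object$coefficients
  dimnames(b) <- list(object$variable_ids, object$response_ids)
  b
}

#' @export
residuals.pls2 <- function(object, block = c("Y", "X"), ...) {
  block <- match.arg(block)
  object$residuals[[block]]
}

#' @export
fitted.pls2 <- function(object, ...) {
  backtransform_y(object, tcrossprod(object$scores, object$y_loadings))
}

backtransform_y <- function(object, Yc_hat) {
  Yh <- sweep(sweep(Yc_hat, 2, object$y_scale, "*"), 2, object$y_center, "+")
  Yh <- invert_transform(Yh, object$settings$y_transform)
  colnames(Yh) <- object$response_ids
  Yh
}

pretreat_x <- function(object, newdata) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_center))
    stop("newdata has ", ncol(X), " columns; model was fitted with ",
         length(object$x_center))
  sweep(sweep(X, 2, object$x_center, "-"), 2, object$x_scale, "/")
}

#' Predict responses from a fitted PLS2 model
#'
#' New samples are pre-treated with the training parameters stored in the
#' model, multiplied by the regression coefficients and back-transformed to
#' the original response units.
#'
#' @param object a \code{"pls2"} model.
#' @param newdata matrix with the training variables; defaults to the
#'   training X.
#' @param ncomp number of latent variables to use (defaults to all fitted).
#' @param type \code{"response"} for predictions in original response units,
#'   \code{"link"} for the treated (centred/scaled/transformed) scale,
#'   \code{"scores"} for projected X-scores \eqn{X_{new} W^*}.
#' @param ... unused.
#' @return numeric matrix.
#' @export
predict.pls2 <- function(object, newdata = NULL, ncomp = NULL,
                         type = c("response", "link", "scores"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$X_raw
  if (is.null(ncomp)) ncomp <- object$ncomp
  if (ncomp > object$ncomp) stop("model has only ", object$ncomp, " components")
  Xc <- pretreat_x(object, newdata)
  k <- seq_len(ncomp)
  if (type == "scores")
    return(Xc %*% object$Wstar[, k, drop = FALSE])
  B <- object$Wstar[, k, drop = FALSE] %*%
    t(object$y_loadings[, k, drop = FALSE])
  Yc_hat <- Xc %*% B
  if (type == "link") {
    colnames(Yc_hat) <- object$response_ids
    return(Yc_hat)
  }
  backtransform_y(object, Yc_hat)
}

#' Explained sum of squares per latent variable
#'
#' Per-component and cumulative fractions of the X- and Y-block sum of squares
#' explained by the model, with \eqn{SSX_j = \|t_j\|^2 \|p_j\|^2} and
#' \eqn{SSY_j = \|t_j\|^2 \|q_j\|^2}; the fractions plus the residual fraction
#' sum to one per block.
#'
#' @param object fitted \code{"pls2"} model.
#' @return list with \code{ssx}, \code{ssy} (per component), block totals and
#'   a summary \code{table}.
#' @export
explained_variance <- function(object) {
  tt <- colSums(object$scores^2)
  ssx <- tt * colSums(object$x_loadings^2)
  ssy <- tt * colSums(object$y_loadings^2)
  totx <- sum(object$x^2); toty <- sum(object$y^2)
  tab <- rbind(X = ssx / totx, `X cumulative` = cumsum(ssx) / totx,
               Y = ssy / toty, `Y cumulative` = cumsum(ssy) / toty)
  colnames(tab) <- paste0("LV", seq_len(object$ncomp))
  list(ssx = ssx, ssy = ssy, total_x = totx, total_y = toty, table = tab)
}

#' Score scatter plot
#'
#' @param x fitted \code{"pls2"} model.
#' @param comps two component indices to plot.
#' @param ... passed to \code{plot()}.
#' @export
plot.pls2 <- function(x, comps = c(1, 2), ...) {
  s <- x$scores
  if (x$ncomp == 1) {
    graphics::plot(s[, 1], seq_len(nrow(s)), xlab = "t[1]", ylab = "sample",
                   ...)
  } else {
    graphics::plot(s[, comps[1]], s[, comps[2]],
                   xlab = paste0("t[", comps[1], "]"),
                   ylab = paste0("t[", comps[2], "]"), ...)
    graphics::abline(h = 0, v = 0, lty = 3)
  }
  invisible(x)
}

# refit on a row subset with identical settings; used by cross-validation and
# permutation machinery.
refit <- function(object, rows, ...) UseMethod("refit")

#' @export
refit.pls2 <- function(object, rows, y = NULL, ...) {
  Y <- if (is.null(y)) object$Y_raw else as.matrix(y)
  s <- object$settings
  suppressWarnings(
    pls2(object$X_raw[rows, , drop = FALSE], Y[rows, , drop = FALSE],
         ncomp = object$ncomp_requested, center = s$center, scale = s$scale,
         y_scale = s$y_scale, y_transform = s$y_transform))
}
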