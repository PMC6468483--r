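#' Variable influence on projection (VIP)
#'
#' For predictor i,
#' \deqn{VIP_i = \sqrt{\frac{P}{SSY} \sum_{j=1}^{A} W_{ij}^2\, SSY_j}}
#' where \eqn{SSY_j = \|t_j\|^2 \|q_j\|^2} is the Y-block sum of squares
#' explained by component j and \eqn{SSY} their total. Because the weight
#' columns are orthonormal the squared scores average to one over the
#' predictors, so 1 is only a rule-of-thumb selection threshold.
#'
#' @param object fitted \code{"pls2"} model.
#' @return data frame with \code{variable} and \code{vip}.
#' @export
vip <- function(object) {
  tt <- colSums(object$scores^2)
  ssy <- tt * colSums(object$y_loadings^2)
  if (sum(ssy) <= 0) stop("model explains no Y-block sum of squares")
  P <- nrow(object$weights)
  v <- sqrt(P * (object$weights^2 %*% ssy) / sum(ssy))
  data.frame(variable = object$variable_ids, vip = drop(v))
}

#' Selectivity ratio with F-distribution threshold
#'
#' For a model with a single predictive latent variable, the selectivity
#' ratio of predictor i is the ratio between its variance explained by that
#' latent variable (from \eqn{T_p P_p^t}) and its variance unexplained by it
#' (from \eqn{T_o P_o^t + E}). Variables whose SR exceeds the F-quantile
#' threshold at level \code{alpha} with (N - 2, N - 3) degrees of freedom are
#' flagged as selected.
#'
#' @param pt a \code{"ptpls2"} model with exactly one predictive component.
#' @param alpha significance level for the threshold.
#' @return data frame with \code{variable}, \code{sr} and \code{selected};
#'   attributes \code{threshold} and \code{alpha}. A variable with zero
#'   predictive variance has \code{sr = 0}; one fully explained by the
#'   predictive component (zero residual variance) gets \code{sr = Inf} and
#'   is flagged in attribute \code{zero_residual}.
#' @export
selectivity_ratio <- function(pt, alpha = 0.05) {
  if (!inherits(pt, "ptpls2")) stop("pt must be a post-transformed model")
  if (pt$Ap != 1)
    stop("the selectivity ratio requires a single predictive latent ",
         "variable (Ap = 1); this model has Ap = ", pt$Ap)
  Xc <- pt$parent$x
  Xhat <- tcrossprod(pt$Tp, pt$Pp)
  Xres <- Xc - Xhat
  expl <- colSums(Xhat^2)
  unexpl <- colSums(Xres^2)
  zero <- unexpl <= .Machine$double.eps * nrow(Xc)
  # zero predictive variance always gives SR 0; +Inf is reserved for
  # variables fully explained by the predictive component
  sr <- ifelse(expl <= .Machine$double.eps * nrow(Xc), 0,
               ifelse(zero, Inf, expl / unexpl))
  thr <- sr_threshold(alpha, nrow(Xc))
  out <- data.frame(variable = pt$parent$variable_ids, sr = sr,
                    selected = sr > thr)
  attr(out, "threshold") <- thr
  attr(out, "alpha") <- alpha
  attr(out, "zero_residual") <- zero
  out
}

#' F-quantile threshold for the selectivity ratio
#'
#' Upper quantile of the F-distribution with (N - 2, N - 3) degrees of
#' freedom; with alpha = 0.05 and N = 38 this gives 1.75.
#'
#' @param alpha significance level.
#' @param N number of training samples.
#' @export
sr_threshold <- function(alpha, N) {
  stats::qf(1 - alpha, df1 = N - 2, df2 = N - 3)
}

#' Correlation loadings
#'
#' Pearson correlations between each latent variable and every predictor and
#' response; the coordinates of the correlation loading plot. Constant
#' variables get correlation 0 with a flag.
#'
#' @param object a \code{"pls2"} or \code{"ptpls2"} model.
#' @param which use \code{"all"} latent variables or only the
#'   \code{"predictive"} ones (post-transformed models).
#' @return matrix of correlations in [-1, 1]; rows are variables then
#'   responses, columns the latent variables; attribute \code{constant} flags
#'   zeroed rows.
#' @export
correlation_loadings <- function(object, which = c("all", "predictive")) {
  which <- match.arg(which)
  if (inherits(object, "ptpls2")) {
    Tm <- if (which == "predictive") object$Tp else object$model$scores
    parent <- object$parent
  } else {
    if (which == "predictive")
      stop("predictive components require a post-transformed model")
    Tm <- object$scores
    parent <- object
  }
  blocks <- cbind(parent$x, parent$y)
  const <- apply(blocks, 2, stats::sd) <= .Machine$double.eps^0.5
  cl <- matrix(0, ncol(blocks), ncol(Tm))
  cl[!const, ] <- stats::cor(blocks[, !const, drop = FALSE], Tm)
  rownames(cl) <- c(parent$variable_ids, parent$response_ids)
  colnames(cl) <- paste0("LV", seq_len(ncol(Tm)))
  attr(cl, "constant") <- const
  cl
}

#' Coordinates of the w*q plot
#'
#' Paired coordinates of the columns of \eqn{W^*} (variables) and the rows of
#' the Y-loading matrix Q (responses) for the first components; the plot is
#' grounded in the identity \eqn{B = W^* Q^t}, so the full inner product of a
#' variable's w* row with a response's q row reproduces its regression
#' coefficient. The display is considered reliable only for models with two
#' or three latent variables.
#'
#' @param object fitted \code{"pls2"} model.
#' @param ncomp number of components to tabulate (default
#'   \code{min(A, 3)}).
#' @return data frame with \code{id}, \code{role} (variable/response) and one
#'   coordinate column per component.
#' @export
wq_coordinates <- function(object, ncomp = NULL) {
  A <- object$ncomp
  if (is.null(ncomp)) ncomp <- min(A, 3L)
  if (A > 3)
    warning("the w*q plot conveys reliable information only for models ",
            "with two or three latent variables (this one has ", A, ")")
  k <- seq_len(ncomp)
  coords <- rbind(object$Wstar[, k, drop = FALSE],
                  object$y_loadings[, k, drop = FALSE])
  out <- data.frame(id = c(object$variable_ids, object$response_ids),
                    role = rep(c("variable", "response"),
                               c(length(object$variable_ids),
                                 length(object$response_ids))))
  colnames(coords) <- paste0("comp", k)
  cbind(out, as.data.frame(coords))
}
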