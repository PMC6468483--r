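#' Dummy class-membership response
#'
#' Codes a label vector as an N x G matrix of ones and zeros (one column per
#' class, ordered by first appearance) and records the autoscaling (unit
#' variance + mean centring) applied before PLS2-DA fitting.
#'
#' @param labels vector or factor of class labels, at least two non-empty
#'   classes.
#' @return list with \code{labels} (factor), \code{levels}, \code{dummy}
#'   (raw 0/1 matrix), \code{scaled}, \code{center}, \code{scale}.
#' @export
make_dummy <- function(labels) {
  f <- factor(labels, levels = unique(as.character(labels)))
  if (nlevels(f) < 2) stop("at least two classes are required")
  D <- stats::model.matrix(~ f - 1)
  colnames(D) <- levels(f)
  attr(D, "assign") <- NULL; attr(D, "contrasts") <- NULL
  sc <- scale_columns(D, "uv", center = TRUE)
  list(labels = f, levels = levels(f), dummy = D, scaled = sc$values,
       center = sc$center, scale = sc$scale)
}

#' Fit a PLS2-DA classifier
#'
#' Two-step classifier: (1) a PLS2 model regressing the autoscaled dummy
#' class-membership response on the predictors; (2) linear discriminant
#' analysis on the N x A score matrix. Class membership is always assessed by
#' the LDA step, never by thresholding the raw PLS2-DA predictions. With
#' balanced classes the leading latent variables maximize the among-group
#' variation.
#'
#' @param X predictor matrix.
#' @param labels class labels (>= 2 non-empty classes).
#' @param ncomp number of latent variables; must stay below N - G to keep the
#'   within-class covariance of the LDA step non-degenerate.
#' @param prior \code{"proportional"} (training frequencies) or
#'   \code{"equal"}.
#' @param center,scale pre-treatment of the X-block as in [pls2()].
#' @return object of class \code{"plsda"} with the PLS2 fit in \code{$pls},
#'   the LDA step in \code{$lda}, and training predictions in
#'   \code{$fitted_class}.
#' @export
plsda <- function(X, labels, ncomp, prior = c("proportional", "equal"),
                  center = TRUE, scale = c("none", "uv", "pareto")) {
  prior <- match.arg(prior)
  scale <- match.arg(scale)
  X <- as.matrix(X)
  dm <- make_dummy(labels)
  G <- length(dm$levels)
  if (ncomp >= nrow(X) - G)
    stop("ncomp must be below N - G = ", nrow(X) - G,
         " to keep LDA non-degenerate; use fewer components")
  fit <- pls2(X, dm$dummy, ncomp = ncomp, center = center, scale = scale,
              y_scale = "uv")
  pr <- if (prior == "proportional") as.numeric(table(dm$labels)) / nrow(X)
        else rep(1 / G, G)
  ld <- MASS::lda(x = fit$scores, grouping = dm$labels, prior = pr)
  fitted_class <- stats::predict(ld, fit$scores)$class
  structure(list(pls = fit, lda = ld, labels = dm$labels,
                 levels = dm$levels, prior = prior,
                 fitted_class = fitted_class,
                 X_raw = X, settings = fit$settings,
                 ncomp = fit$ncomp, ncomp_requested = ncomp),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS2-DA classifier:", length(x$levels), "classes,",
      x$ncomp, "latent variable(s)\n")
  k <- cohens_kappa(x$labels, x$fitted_class)
  cat("Cohen's kappa in calculation:", round(k, 3), "\n")
  invisible(x)
}

#' Predict class membership from a PLS2-DA model
#'
#' New samples are projected onto the latent space (training pre-treatment,
#' \eqn{X_{new} W^*}) and classified by the LDA step.
#'
#' @param object a \code{"plsda"} model.
#' @param newdata matrix of new samples; defaults to training X.
#' @param ... unused.
#' @return list with \code{class}, \code{posterior} and \code{scores}.
#' @export
predict.plsda <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$X_raw
  sc <- predict(object$pls, newdata, type = "scores")
  pr <- stats::predict(object$lda, sc)
  list(class = pr$class, posterior = pr$posterior, scores = sc)
}

#' @export
refit.plsda <- function(object, rows, y = NULL, ...) {
  lab <- if (is.null(y)) object$labels else y
  plsda(object$X_raw[rows, , drop = FALSE], droplevels(factor(lab[rows])),
        ncomp = object$ncomp_requested, prior = object$prior,
        center = object$settings$center, scale = object$settings$scale)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} between two
#' label vectors, with expected agreement from the marginal products.
#'
#' @param true_labels,predicted_labels vectors of equal length over a shared
#'   label universe.
#' @return kappa in [-1, 1].
#' @export
cohens_kappa <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  lev <- union(unique(as.character(true_labels)),
               unique(as.character(predicted_labels)))
  a <- factor(as.character(true_labels), levels = lev)
  b <- factor(as.character(predicted_labels), levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe <= .Machine$double.eps)
    stop("expected agreement is 1 (single shared class): kappa undefined")
  (po - pe) / (1 - pe)
}

#' Cross-validated Cohen's kappa
#'
#' k-fold CV of a PLS2-DA classifier; each training fold refits the full
#' pipeline (pre-treatment, PLS2, LDA) and the held-out fold is predicted.
#'
#' @param object a \code{"plsda"} model.
#' @param k folds.
#' @param seed fold seed.
#' @param folds optional explicit assignment.
#' @return list with \code{kappa} and the out-of-fold \code{class}
#'   predictions.
#' @export
kappa_cv <- function(object, k = 7, seed = 1, folds = NULL) {
  N <- nrow(object$X_raw)
  if (is.null(folds)) folds <- make_folds(N, k, seed)
  pred <- rep(NA_character_, N)
  for (f in sort(unique(folds))) {
    test <- which(folds == f); train <- which(folds != f)
    m <- tryCatch(suppressWarnings(refit(object, train)),
                  error = function(e) NULL)
    if (is.null(m)) next  # fold lost a class; its samples count as errors
    pred[test] <- as.character(
      predict(m, object$X_raw[test, , drop = FALSE])$class)
  }
  pred[is.na(pred)] <- "<unassigned>"
  list(kappa = cohens_kappa(object$labels, pred), class = pred,
       folds = folds)
}

#' Permutation test for a PLS2-DA classifier
#'
#' Class labels are permuted; training kappa and 7-fold CV kappa are
#' recomputed per permutation with the full pipeline.
#'
#' @inheritParams permutation_test
#' @param object a \code{"plsda"} model.
#' @return object of class \code{"perm_test"} with statistics \code{kappa}
#'   and \code{kappa_cv}.
#' @export
permutation_test_da <- function(object, n_perm = 1000, seed = 1, k = 7) {
  N <- nrow(object$X_raw)
  set.seed(seed)
  perms <- t(replicate(n_perm, sample.int(N)))
  folds <- make_folds(N, k, seed)
  obs_k <- cohens_kappa(object$labels, object$fitted_class)
  obs_kcv <- kappa_cv(object, folds = folds)$kappa
  null_k <- null_kcv <- rep(NA_real_, n_perm)
  for (b in seq_len(n_perm)) {
    mb <- suppressWarnings(refit(object, seq_len(N),
                                 y = object$labels[perms[b, ]]))
    null_k[b] <- cohens_kappa(mb$labels, mb$fitted_class)
    null_kcv[b] <- kappa_cv(mb, folds = folds)$kappa
  }
  pv <- function(null, obs) (sum(null >= obs) + 1) / (n_perm + 1)
  out <- list(observed = c(kappa = obs_k, kappa_cv = obs_kcv),
              null = list(kappa = null_k, kappa_cv = null_kcv),
              p = c(kappa = pv(null_k, obs_k),
                    kappa_cv = pv(null_kcv, obs_kcv)),
              n_perm = n_perm, seed = seed)
  class(out) <- "perm_test"
  out
}

#' Select the number of latent variables for PLS2-DA
#'
#' First local maximum of the 7-fold CV kappa over component counts, subject
#' to passing the label-permutation test at level \code{alpha}.
#'
#' @param X predictor matrix.
#' @param labels class labels.
#' @param ncomp_max largest component count to scan.
#' @param k,n_perm,alpha,seed as in [select_ncomp()].
#' @param ... passed to [plsda()].
#' @return object of class \code{"validation_report"}.
#' @export
select_ncomp_da <- function(X, labels, ncomp_max, k = 7, n_perm = 99,
                            alpha = 0.05, seed = 1, ...) {
  X <- as.matrix(X)
  folds <- make_folds(nrow(X), k, seed)
  kcv <- ktr <- rep(NA_real_, ncomp_max)
  fits <- vector("list", ncomp_max)
  for (a in seq_len(ncomp_max)) {
    fa <- suppressWarnings(plsda(X, labels, ncomp = a, ...))
    fits[[a]] <- fa
    ktr[a] <- cohens_kappa(fa$labels, fa$fitted_class)
    kcv[a] <- kappa_cv(fa, folds = folds)$kappa
    if (fa$ncomp < a) { kcv <- kcv[seq_len(a)]; ktr <- ktr[seq_len(a)]; break }
  }
  amax <- length(kcv)
  cands <- integer(0)
  for (a in seq_len(amax))
    if (a == amax || kcv[a] >= kcv[a + 1]) cands <- c(cands, a)
  chosen <- NA_integer_; perm <- NULL
  for (a in cands) {
    pt <- permutation_test_da(fits[[a]], n_perm = n_perm, seed = seed, k = k)
    perm <- pt
    if (pt$p["kappa_cv"] <= alpha) { chosen <- a; break }
  }
  status <- if (is.na(chosen))
    "failure: no component count passes the permutation test" else "ok"
  out <- list(per_A = data.frame(A = seq_len(amax), kappa = ktr,
                                 kappa_cv = kcv),
              chosen_A = chosen, status = status, perm = perm,
              alpha = alpha, seed = seed, folds = folds)
  class(out) <- "validation_report"
  out
}
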