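#' Filter variables by VIP threshold
#'
#' @param model fitted \code{"pls2"} model (or \code{"plsda"}, whose PLS part
#'   is used).
#' @param threshold variables with VIP greater than or equal to the threshold
#'   are retained (ties at the threshold are kept).
#' @return logical mask over the variables; never empties the set (the top-1
#'   variable is kept, with attribute \code{guard = TRUE}).
#' @export
vip_filter <- function(model, threshold) {
  if (inherits(model, "plsda")) model <- model$pls
  v <- vip(model)$vip
  mask <- v >= threshold
  guard <- FALSE
  if (!any(mask)) {
    mask[which.max(v)] <- TRUE
    guard <- TRUE
  }
  attr(mask, "guard") <- guard
  mask
}

#' Monte-Carlo stability selection with VIP-filtered sub-models
#'
#' Draws random subsamples of the rows (independent inclusion with
#' probability \code{inclusion_prob}), fits a PLS2(-DA) model on each, tunes
#' the component count and VIP threshold by k-fold cross-validation inside the
#' subsample (maximizing CV kappa for classification, CV Q2 for regression),
#' and counts how often each variable survives the best model's VIP filter.
#' Variables selected in more than half of the sub-models are flagged as
#' relevant. Out-of-subsample rows are predicted by each best sub-model to
#' build a performance distribution with a percentile confidence interval.
#'
#' @param X predictor matrix.
#' @param y quantitative response (regression) or factor/character labels
#'   (classification).
#' @param n_sub number of Monte-Carlo subsamples.
#' @param inclusion_prob per-sample inclusion probability.
#' @param ncomp_grid candidate component counts for the inner optimization.
#' @param vip_grid candidate VIP thresholds.
#' @param k folds of the inner cross-validation.
#' @param seed integer seed; the whole procedure is reproducible from it.
#' @param ... passed to [pls2()] / [plsda()].
#' @return object of class \code{"stability_selection"}: per-variable
#'   selection \code{frequencies}, \code{relevant} mask (frequency > 0.5),
#'   the out-of-subsample performance distribution with a 95 percent
#'   percentile CI, and a log of degenerate subsamples that were redrawn.
#' @export
stability_selection <- function(X, y, n_sub = 100, inclusion_prob = 0.70,
                                ncomp_grid = 1:3,
                                vip_grid = c(0.8, 1.0, 1.2, 1.5),
                                k = 7, seed = 1, ...) {
  X <- as.matrix(X)
  N <- nrow(X); P <- ncol(X)
  classification <- is.factor(y) || is.character(y)
  if (classification) y <- factor(y, levels = unique(as.character(y)))
  set.seed(seed)
  counts <- numeric(P)
  oob_perf <- rep(NA_real_, n_sub)
  redraws <- 0L
  for (b in seq_len(n_sub)) {
    repeat {
      rows <- which(stats::runif(N) < inclusion_prob)
      ok <- length(rows) > k && length(rows) < N &&
        (!classification || all(table(droplevels(y[rows])) >= 2) &&
           nlevels(droplevels(y[rows])) == nlevels(y))
      if (ok) break
      redraws <- redraws + 1L
    }
    oob <- setdiff(seq_len(N), rows)
    best <- NULL
    folds <- make_folds(length(rows), k, seed = seed + b)
    for (a in ncomp_grid) {
      base <- tryCatch(suppressWarnings(
        if (classification) plsda(X[rows, , drop = FALSE], y[rows],
                                  ncomp = a, ...)
        else pls2(X[rows, , drop = FALSE],
                  matrix(y[rows], ncol = 1), ncomp = a, ...)),
        error = function(e) NULL)
      if (is.null(base)) next
      for (thr in vip_grid) {
        mask <- vip_filter(base, thr)
        sub <- tryCatch(suppressWarnings(
          if (classification) plsda(X[rows, mask, drop = FALSE], y[rows],
                                    ncomp = min(a, sum(mask)), ...)
          else pls2(X[rows, mask, drop = FALSE],
                    matrix(y[rows], ncol = 1),
                    ncomp = min(a, sum(mask)), ...)),
          error = function(e) NULL)
        if (is.null(sub)) next
        score <- tryCatch(
          if (classification) kappa_cv(sub, folds = folds)$kappa
          else mean(cv_q2(sub, folds = folds)$q2),
          error = function(e) -Inf)
        if (is.null(best) || score > best$score)
          best <- list(score = score, mask = mask, model = sub)
      }
    }
    if (is.null(best)) next
    counts <- counts + best$mask
    if (length(oob) > 0) {
      Xo <- X[oob, best$mask, drop = FALSE]
      oob_perf[b] <- if (classification) {
        cohens_kappa(y[oob], predict(best$model, Xo)$class)
      } else {
        pr <- predict(best$model, Xo)
        1 - sum((y[oob] - pr)^2) / sum((y[oob] - mean(y[rows]))^2)
      }
    }
  }
  freq <- counts / n_sub
  names(freq) <- colnames(X) %||% paste0("V", seq_len(P))
  ci <- stats::quantile(oob_perf, c(0.025, 0.975), na.rm = TRUE)
  out <- list(frequencies = freq, relevant = freq > 0.5, n_sub = n_sub,
              inclusion_prob = inclusion_prob,
              oob_performance = oob_perf, oob_ci = ci,
              task = if (classification) "classification" else "regression",
              redraws = redraws, seed = seed)
  class(out) <- "stability_selection"
  out
}

#' @export
print.stability_selection <- function(x, ...) {
  cat("Stability selection over", x$n_sub, "subsamples (",
      x$task, ")\n")
  cat(sum(x$relevant), "variable(s) selected in more than half of the",
      "sub-models\n")
  cat(sprintf("out-of-subsample performance: median %.3f, 95%% CI %.2f-%.2f\n",
              stats::median(x$oob_performance, na.rm = TRUE),
              x$oob_ci[1], x$oob_ci[2]))
  invisible(x)
}

#' Uninformative variable elimination (UVE-PLS)
#'
#' Appends P artificial noise variables (seeded normal, scaled to
#' \code{noise_magnitude} times each column's scale) to the data, runs a
#' leave-one-out jackknife of the PLS2 regression coefficients on the
#' augmented matrix, and computes the reliability
#' \eqn{c_j = mean(b_j)/sd(b_j)} of each coefficient across the rounds.
#' Experimental variables whose |reliability| does not exceed the largest
#' |reliability| observed among the artificial variables are eliminated.
#'
#' @param X predictor matrix.
#' @param y single-column quantitative response.
#' @param ncomp latent variables for each jackknife fit.
#' @param noise_magnitude scale of the artificial variables relative to the
#'   data columns; small enough to leave the fit unchanged.
#' @param seed integer seed for the artificial noise.
#' @param ... passed to [pls2()].
#' @return list with \code{retained} (logical mask over experimental
#'   variables), \code{reliability}, \code{cutoff} and
#'   \code{noise_reliability}.
#' @export
uve_pls <- function(X, y, ncomp, noise_magnitude = 1e-10, seed = 1, ...) {
  X <- as.matrix(X)
  y <- as.matrix(y)
  if (ncol(y) != 1) stop("UVE-PLS is defined for a single response")
  N <- nrow(X); P <- ncol(X)
  if (N < 3) stop("leave-one-out jackknife needs at least 3 samples")
  set.seed(seed)
  colsc <- apply(X, 2, stats::sd)
  colsc[colsc == 0] <- 1
  noise <- matrix(stats::rnorm(N * P), N, P) *
    rep(noise_magnitude * colsc, each = N)
  Xa <- cbind(X, noise)
  Bm <- matrix(NA_real_, N, 2 * P)
  for (i in seq_len(N)) {
    m <- suppressWarnings(pls2(Xa[-i, , drop = FALSE], y[-i, , drop = FALSE],
                               ncomp = ncomp, ...))
    Bm[i, ] <- m$coefficients[, 1]
  }
  rel <- colMeans(Bm) / apply(Bm, 2, stats::sd)
  c_exp <- rel[seq_len(P)]
  c_noise <- rel[P + seq_len(P)]
  cutoff <- max(abs(c_noise))
  list(retained = abs(c_exp) > cutoff, reliability = c_exp,
       cutoff = cutoff, noise_reliability = c_noise)
}
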