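#' Build cross-validation folds
#'
#' @param N number of samples.
#' @param k number of folds.
#' @param seed integer seed (random type).
#' @param type \code{"random"} (seeded near-equal partition) or
#'   \code{"venetian"} (every k-th sample).
#' @return integer vector of fold assignments.
#' @export
make_folds <- function(N, k = 7, seed = 1, type = c("random", "venetian")) {
  type <- match.arg(type)
  if (k < 2 || k > N) stop("k must be between 2 and N")
  if (type == "venetian") return(rep_len(seq_len(k), N))
  set.seed(seed)
  sample(rep_len(seq_len(k), N))
}

#' Cross-validated Q2
#'
#' Q2 per response from k-fold cross-validation:
#' \eqn{Q^2_m = 1 - PRESS_m / SS_m}, with PRESS accumulated from out-of-fold
#' predictions and SS about the training-fold mean. Pre-treatment (centring,
#' scaling, response transform) is re-estimated inside each training fold, so
#' no test-fold information leaks into the fitted parameters. Both PRESS and
#' SS are evaluated on the transformed response scale (the scale the model is
#' fitted on).
#'
#' @param object fitted model (\code{pls2}, \code{ocpls2} or \code{kpls2});
#'   each fold is refit with the model's own settings.
#' @param k number of folds.
#' @param seed seed for the fold partition.
#' @param folds optional explicit fold assignment (overrides \code{k}/seed).
#' @return list with \code{q2} (per response), \code{press}, \code{ss},
#'   \code{predictions} (out-of-fold, transformed scale), \code{folds} and
#'   \code{fold_centers} (per-fold X-centre vectors, for leakage audits).
#' @export
cv_q2 <- function(object, k = 7, seed = 1, folds = NULL) {
  N <- nrow(object$X_raw)
  if (is.null(folds)) folds <- make_folds(N, k, seed)
  tr <- object$settings$y_transform
  Yt <- apply_transform(object$Y_raw, tr)
  M <- ncol(Yt)
  press <- ss <- numeric(M)
  preds <- matrix(NA_real_, N, M)
  centers <- list()
  for (f in sort(unique(folds))) {
    test <- which(folds == f); train <- which(folds != f)
    m <- refit(object, train)
    centers[[as.character(f)]] <- m$x_center
    lk <- predict(m, object$X_raw[test, , drop = FALSE], type = "link")
    yhat <- sweep(sweep(lk, 2, m$y_scale, "*"), 2, m$y_center, "+")
    preds[test, ] <- yhat
    mu_train <- colMeans(Yt[train, , drop = FALSE])
    press <- press + colSums((Yt[test, , drop = FALSE] - yhat)^2)
    ss <- ss + colSums(sweep(Yt[test, , drop = FALSE], 2, mu_train)^2)
  }
  q2 <- 1 - press / ss
  names(q2) <- object$response_ids
  list(q2 = q2, press = press, ss = ss, predictions = preds,
       folds = folds, fold_centers = centers)
}

#' Permutation test on the Y-response
#'
#' Rows of Y are permuted jointly; the full pipeline (fit and, for Q2, the
#' cross-validation loop with fold-wise pre-treatment) is recomputed for every
#' permutation. P-values use the add-one correction
#' \eqn{p = (\#\{null \ge observed\} + 1) / (n_{perm} + 1)}, hence are never
#' smaller than \eqn{1/(n_{perm}+1)}.
#'
#' @param object fitted regression model.
#' @param n_perm number of random permutations.
#' @param seed seed for permutations and fold assignment.
#' @param k folds for the Q2 statistic.
#' @param permutations optional matrix of row permutations (one per row),
#'   e.g. the full enumeration for small N; overrides \code{n_perm}.
#' @param statistics which statistics to test.
#' @return object of class \code{"perm_test"} with observed values, null
#'   distributions and p-values per statistic (response-averaged R2 and Q2).
#' @export
permutation_test <- function(object, n_perm = 1000, seed = 1, k = 7,
                             permutations = NULL,
                             statistics = c("r2", "q2")) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  N <- nrow(object$X_raw)
  set.seed(seed)
  if (is.null(permutations)) {
    permutations <- t(replicate(n_perm, sample.int(N)))
  } else permutations <- as.matrix(permutations)
  n_perm <- nrow(permutations)
  folds <- make_folds(N, k, seed)
  obs_r2 <- mean(r_squared(object))
  obs_q2 <- if ("q2" %in% statistics)
    mean(cv_q2(object, folds = folds)$q2) else NA_real_
  null_r2 <- null_q2 <- rep(NA_real_, n_perm)
  for (b in seq_len(n_perm)) {
    yb <- object$Y_raw[permutations[b, ], , drop = FALSE]
    mb <- refit(object, seq_len(N), y = yb)
    if ("r2" %in% statistics) null_r2[b] <- mean(r_squared(mb))
    if ("q2" %in% statistics) null_q2[b] <- mean(cv_q2(mb, folds = folds)$q2)
  }
  pv <- function(null, obs) (sum(null >= obs) + 1) / (n_perm + 1)
  out <- list(observed = c(r2 = obs_r2, q2 = obs_q2),
              null = list(r2 = null_r2, q2 = null_q2),
              p = c(r2 = if ("r2" %in% statistics) pv(null_r2, obs_r2)
                         else NA_real_,
                    q2 = if ("q2" %in% statistics) pv(null_q2, obs_q2)
                         else NA_real_),
              n_perm = n_perm, seed = seed)
  class(out) <- "perm_test"
  out
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test (", x$n_perm, " permutations)\n", sep = "")
  for (s in names(x$p)) if (!is.na(x$p[s]))
    cat(sprintf("  %s: observed = %.4f, p = %.4g\n",
                toupper(s), x$observed[s], x$p[s]))
  invisible(x)
}

#' Select the number of latent variables
#'
#' Scans component counts 1..\code{ncomp_max}, computing R2 and
#' cross-validated Q2 per response, and picks the first local maximum of the
#' response-averaged Q2 that also passes the permutation test at level
#' \code{alpha}. If no candidate passes, the report carries a failure status
#' rather than an error.
#'
#' @param X,Y training data.
#' @param ncomp_max largest component count to scan.
#' @param method \code{"pls2"}, \code{"ocpls2"} or \code{"kpls2"}.
#' @param Z constraint matrix (oCPLS2 only).
#' @param kernel [kernel_spec()] (KPLS2 only).
#' @param k CV folds.
#' @param n_perm permutations for the test at each candidate.
#' @param alpha significance level.
#' @param seed seed for folds and permutations.
#' @param ... pre-treatment arguments passed to the fit function.
#' @return object of class \code{"validation_report"} with the per-A table,
#'   \code{chosen_A} (NA on failure), permutation p-values and status.
#' @export
select_ncomp <- function(X, Y, ncomp_max, method = c("pls2", "ocpls2",
                                                     "kpls2"),
                         Z = NULL, kernel = NULL, k = 7, n_perm = 99,
                         alpha = 0.05, seed = 1, ...) {
  method <- match.arg(method)
  fit_fun <- switch(method,
    pls2 = function(a) pls2(X, Y, ncomp = a, ...),
    ocpls2 = function(a) ocpls2(X, Y, Z = Z, ncomp = a, ...),
    kpls2 = function(a) kpls2(X, Y, kernel = kernel %||%
                                kernel_spec("linear"), ncomp = a, ...))
  full <- suppressWarnings(fit_fun(ncomp_max))
  amax <- full$ncomp
  folds <- make_folds(nrow(as.matrix(X)), k, seed)
  q2m <- r2m <- matrix(NA_real_, amax, length(full$response_ids),
                       dimnames = list(NULL, full$response_ids))
  for (a in seq_len(amax)) {
    fa <- suppressWarnings(fit_fun(a))
    r2m[a, ] <- r_squared(fa)
    q2m[a, ] <- cv_q2(fa, folds = folds)$q2
  }
  q2bar <- rowMeans(q2m)
  note <- NULL
  cands <- integer(0)
  for (a in seq_len(amax)) {
    if (a == amax || q2bar[a] >= q2bar[a + 1]) cands <- c(cands, a)
  }
  if (length(cands) > 0 && cands[1] == amax && amax > 1)
    note <- "no interior maximum: Q2 increases up to ncomp_max"
  chosen <- NA_integer_
  perm <- NULL
  for (a in cands) {
    fa <- suppressWarnings(fit_fun(a))
    pt <- permutation_test(fa, n_perm = n_perm, seed = seed, k = k)
    perm <- pt
    if (!is.na(pt$p["q2"]) && pt$p["q2"] <= alpha) { chosen <- a; break }
  }
  status <- if (is.na(chosen))
    "failure: no component count passes the permutation test" else "ok"
  out <- list(per_A = data.frame(A = seq_len(amax), R2 = r2m, Q2 = q2m,
                                 Q2_mean = q2bar),
              chosen_A = chosen, status = status, note = note,
              perm = perm, alpha = alpha, seed = seed, folds = folds)
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Component selection (first maximum of Q2 + permutation test)\n")
  print(round(as.matrix(x$per_A[, -1, drop = FALSE]), 4))
  if (!is.na(x$chosen_A)) cat("chosen A:", x$chosen_A, "\n")
  else cat(x$status, "\n")
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Root mean squared error in calculation or prediction (SDEC / SDEP)
#'
#' \eqn{\sqrt{\sum (y - \hat y)^2 / n}} in original response units; callers
#' must pass back-transformed values (the \code{predict} methods already
#' return original units).
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @param context \code{"calculation"} (training, SDEC) or
#'   \code{"prediction"} (test set, SDEP); affects only the label.
#' @return named numeric scalar.
#' @export
error_metrics <- function(y_true, y_pred,
                          context = c("calculation", "prediction")) {
  context <- match.arg(context)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  v <- sqrt(mean((as.numeric(y_true) - as.numeric(y_pred))^2))
  names(v) <- if (context == "calculation") "SDEC" else "SDEP"
  v
}

#' Stratified train/test split on a quantitative response
#'
#' Bins the response into quantile strata and assigns a seeded random
#' fraction of each stratum to the training set, so both sets cover the
#' response range. The total training size is \code{round(N *
#' train_fraction)}, allocated across strata by largest remainder.
#'
#' @param y quantitative response.
#' @param train_fraction fraction of samples assigned to training.
#' @param n_strata number of quantile strata.
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
stratified_split <- function(y, train_fraction, n_strata = 5, seed = 1) {
  y <- as.numeric(y)
  N <- length(y)
  if (train_fraction >= 1) return(list(train = seq_len(N), test = integer(0)))
  breaks <- unique(stats::quantile(y, probs = seq(0, 1,
                                                  length.out = n_strata + 1)))
  if (length(breaks) - 1 < n_strata)
    warning("empty or duplicated strata merged with neighbours")
  strata <- cut(y, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  set.seed(seed)
  sizes <- tabulate(strata)
  ideal <- sizes * train_fraction
  base <- floor(ideal)
  total <- round(N * train_fraction)
  extra <- total - sum(base)
  if (extra > 0) {
    ord <- order(ideal - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  train <- unlist(lapply(seq_along(sizes), function(s) {
    idx <- which(strata == s)
    sample(idx, min(base[s], length(idx)))
  }))
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(N), train))
}
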