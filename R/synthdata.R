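#' Simulate data with planted latent structure
#'
#' Generates a sample-by-variable matrix built from a low-rank predictive part,
#' an optional "structured noise" part orthogonal to the response, and i.i.d.
#' residual noise:
#' \deqn{X = T_p P_p^t + T_o P_o^t + E, \qquad Y = T_p Q_p^t + F.}
#' Orthogonal scores are drawn orthogonal to both the predictive scores and the
#' realized response, so the planted split matches the decomposition that
#' post-transformation is designed to recover. Loading vectors are sparse
#' \eqn{\pm 1} patterns on disjoint variable blocks, normalized to unit length,
#' hence mutually orthogonal by construction.
#'
#' @param N,P,M numbers of samples, predictors, responses.
#' @param n_pred,n_orth numbers of planted predictive and orthogonal latent
#'   components; \code{n_pred + n_orth <= min(N - 1, P)}.
#' @param loading_sparsity fraction of variables carrying each component.
#' @param effect_size standard deviation of the planted score vectors.
#' @param noise_sd standard deviation of the i.i.d. residuals in both blocks.
#' @param response \code{"linear"} or \code{"quadratic"} (response built from
#'   the squared first predictive score; used to exercise kernel models).
#' @param classes optional integer: instead of a quantitative response, return
#'   class labels obtained by shifting the predictive score means by
#'   \code{class_shift} per class.
#' @param class_shift mean separation (in score standard deviations) between
#'   consecutive classes.
#' @param seed integer seed; the output is fully reproducible from it.
#' @return list with \code{X}, \code{Y} (matrix, or factor of labels when
#'   \code{classes} is given) and \code{truth} carrying the planted scores,
#'   loadings and the informative-variable masks.
#' @export
sim_latent_data <- function(N = 40, P = 50, M = 1, n_pred = 1, n_orth = 1,
                            loading_sparsity = 0.2, effect_size = 3,
                            noise_sd = 0.3, response = c("linear", "quadratic"),
                            classes = NULL, class_shift = 3, seed = NULL) {
  response <- match.arg(response)
  if (!is.null(seed)) set.seed(seed)
  K <- n_pred + n_orth
  if (K > min(N - 1, P))
    stop("n_pred + n_orth must not exceed min(N - 1, P)")
  block <- max(1L, ceiling(loading_sparsity * P))
  if (K * block > P)
    stop("loading_sparsity too large for ", K, " disjoint component blocks")

  load_mat <- matrix(0, P, K)
  for (j in seq_len(K)) {
    idx <- ((j - 1L) * block + 1L):(j * block)
    load_mat[idx, j] <- sample(c(-1, 1), block, replace = TRUE)
    load_mat[, j] <- load_mat[, j] / sqrt(sum(load_mat[, j]^2))
  }
  Pp <- load_mat[, seq_len(n_pred), drop = FALSE]
  Po <- if (n_orth > 0) load_mat[, n_pred + seq_len(n_orth), drop = FALSE]
        else matrix(0, P, 0)

  labels <- NULL
  Tp <- matrix(stats::rnorm(N * n_pred), N, n_pred)
  if (!is.null(classes)) {
    labels <- factor(rep_len(paste0("C", seq_len(classes)), N))
    # orthogonal contrasts give up to classes - 1 planted discriminant axes
    ctr <- stats::contr.helmert(classes)
    ctr <- scale(ctr, center = TRUE, scale = apply(ctr, 2, stats::sd))
    ncls <- min(n_pred, classes - 1L)
    for (j in seq_len(ncls))
      Tp[, j] <- Tp[, j] + class_shift * ctr[as.integer(labels), j]
  }
  Tp <- scale(Tp, center = TRUE, scale = FALSE) * effect_size

  if (is.null(labels)) {
    Qp <- matrix(stats::runif(M * n_pred, 0.5, 1.5) *
                   sample(c(-1, 1), M * n_pred, replace = TRUE), M, n_pred)
    Fres <- matrix(stats::rnorm(N * M, sd = noise_sd), N, M)
    Y <- if (response == "linear") tcrossprod(Tp, Qp) + Fres
         else (Tp[, 1]^2 - mean(Tp[, 1]^2)) %*% t(Qp[, 1, drop = FALSE]) / effect_size + Fres
  } else {
    Qp <- NULL
    Y <- stats::model.matrix(~ labels - 1)  # used only to orthogonalize To
  }

  if (n_orth > 0) {
    To <- matrix(stats::rnorm(N * n_orth), N, n_orth)
    base <- cbind(rep(1, N), Tp, Y)
    To <- To - base %*% qr.coef(qr(base), To)
    To <- qr.Q(qr(To)) * sqrt(N - 1) * effect_size
  } else To <- matrix(0, N, 0)

  X <- tcrossprod(Tp, Pp) + tcrossprod(To, Po) +
    matrix(stats::rnorm(N * P, sd = noise_sd), N, P)
  dimnames(X) <- list(paste0("s", seq_len(N)), paste0("v", seq_len(P)))

  truth <- list(Tp = Tp, To = To, Pp = Pp, Po = Po, Qp = Qp,
                informative = rowSums(abs(Pp)) > 0,
                orth_vars = if (n_orth > 0) rowSums(abs(Po)) > 0
                            else rep(FALSE, P))
  out <- list(X = X, truth = truth,
              design = list(N = N, P = P, M = M, n_pred = n_pred,
                            n_orth = n_orth, loading_sparsity = loading_sparsity,
                            effect_size = effect_size, noise_sd = noise_sd,
                            response = response, seed = seed))
  if (is.null(labels)) {
    dimnames(Y) <- list(rownames(X), paste0("y", seq_len(M)))
    out$Y <- Y
  } else out$Y <- labels
  out
}

#' Simulate a paired design with a nuisance factor
#'
#' Emulates a two-factor layout where samples come in pairs (e.g. two
#' specimens per subject under two conditions): a quantitative response drives
#' the predictive score, while a paired dummy factor shifts a designated
#' variable subset, creating structured variation unrelated to the response.
#' The dummy coding is returned as the constraint matrix \code{Z} for
#' orthogonally-constrained fits.
#'
#' @param N even number of samples (N/2 pairs).
#' @param P number of variables.
#' @param nuisance_effect standard deviation of the nuisance component's
#'   scores, on the same scale as \code{effect_size} (0 disables it).
#' @param nuisance_frac fraction of variables carrying the nuisance-specific
#'   part of the loading.
#' @param nuisance_overlap cosine between the nuisance loading and the
#'   predictive loading; a non-zero overlap makes the factor perturb
#'   response-tracking variables, which is what lets it confound an
#'   unconstrained fit.
#' @param effect_size,noise_sd,loading_sparsity,response as in
#'   [sim_latent_data()].
#' @param seed integer seed.
#' @return list with \code{X}, \code{Y} (single-column response), \code{Z}
#'   (N x 1 raw 0/1 dummy) and \code{truth}.
#' @export
sim_paired_data <- function(N = 40, P = 50, nuisance_effect = 3,
                            nuisance_frac = 0.2, nuisance_overlap = 0.5,
                            effect_size = 3, noise_sd = 0.3,
                            loading_sparsity = 0.2,
                            response = c("linear", "quadratic"), seed = NULL) {
  response <- match.arg(response)
  if (N %% 2 != 0) stop("paired design requires an even N")
  if (!is.null(seed)) set.seed(seed)
  npair <- N / 2
  pair_val <- stats::rnorm(npair)
  t_pred <- rep(pair_val, each = 2)
  t_pred <- (t_pred - mean(t_pred)) * effect_size
  z <- rep(c(0, 1), npair)

  block <- max(1L, ceiling(loading_sparsity * P))
  p_pred <- numeric(P)
  p_pred[seq_len(block)] <- sample(c(-1, 1), block, replace = TRUE)
  p_pred <- p_pred / sqrt(sum(p_pred^2))
  n_nui <- max(1L, ceiling(nuisance_frac * P))
  nui_idx <- (P - n_nui + 1L):P
  p_only <- numeric(P)
  p_only[nui_idx] <- sample(c(-1, 1), n_nui, replace = TRUE)
  p_only <- p_only / sqrt(sum(p_only^2))
  # the nuisance factor perturbs some of the same variables that track the
  # response: fixed cosine overlap with the predictive loading
  p_nui <- nuisance_overlap * p_pred +
    sqrt(1 - nuisance_overlap^2) * p_only

  y <- if (response == "linear") t_pred else t_pred^2 - mean(t_pred^2)
  y <- y + stats::rnorm(N, sd = noise_sd)
  # nuisance scores on the same unit-sd scale as the predictive ones, so
  # nuisance_effect and effect_size are directly comparable
  z_score <- (z - mean(z)) / stats::sd(z)
  X <- tcrossprod(t_pred, p_pred) +
    nuisance_effect * tcrossprod(z_score, p_nui) +
    matrix(stats::rnorm(N * P, sd = noise_sd), N, P)
  dimnames(X) <- list(paste0("s", seq_len(N)), paste0("v", seq_len(P)))
  Y <- matrix(y, ncol = 1, dimnames = list(rownames(X), "y1"))
  Z <- matrix(z, ncol = 1, dimnames = list(rownames(X), "factor"))
  list(X = X, Y = Y, Z = Z,
       truth = list(t_pred = t_pred, p_pred = p_pred, p_nui = p_nui,
                    nuisance_vars = nui_idx,
                    informative = abs(p_pred) > 0),
       design = list(N = N, P = P, nuisance_effect = nuisance_effect,
                     nuisance_frac = nuisance_frac, effect_size = effect_size,
                     noise_sd = noise_sd, response = response, seed = seed))
}
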