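fit_ref <- function(seed = 11, ncomp = 3, N = 20, P = 8, M = 2) {
  set.seed(seed)
  X <- matrix(rnorm(N * P), N, P)
  Y <- matrix(rnorm(N * M), N, M)
  pls2(X, Y, ncomp = ncomp)
}

test_that("identity transform reproduces the parent decomposition", {
  m <- fit_ref()
  tw <- transform_weights(m, diag(3))
  expect_equal(tw$scores, m$scores)
  expect_equal(tw$x_loadings, m$x_loadings)
  expect_equal(tw$coefficients, m$coefficients)
})

test_that("random non-singular weight transforms leave B and residuals unchanged", {
  m <- fit_ref()
  set.seed(99)
  for (i in 1:10) {
    H <- matrix(rnorm(9), 3, 3)
    tw <- transform_weights(m, H)
    expect_lt(max(abs(tw$coefficients - m$coefficients)), 1e-10)
    expect_lt(max(abs(tw$residuals$X - m$residuals$X)), 1e-10)
    expect_lt(max(abs(tw$residuals$Y - m$residuals$Y)), 1e-10)
  }
  expect_error(transform_weights(m, matrix(1, 3, 3)), "singular")
})

test_that("permutation transforms span the same score space", {
  m <- fit_ref()
  H <- diag(3)[, c(2, 3, 1)]
  tw <- transform_weights(m, H)
  expect_lt(max(abs(tw$coefficients - m$coefficients)), 1e-10)
  proj <- function(S) {
    Qm <- qr.Q(qr(S))
    tcrossprod(Qm)
  }
  expect_lt(max(abs(proj(tw$scores) - proj(m$scores))), 1e-8)
})

test_that("single-response one-component model has nothing to remove", {
  set.seed(12)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- X[, 1] + rnorm(20, sd = 0.2)
  m <- pls2(X, y, ncomp = 1)
  pt <- post_transform(m)
  expect_equal(pt$Ap, 1)
  expect_equal(pt$Ao, 0)
  expect_equal(pt$Tp[, 1], m$scores[, 1])
})

test_that("reference structured-noise design splits into 1 + 1 and recovers the planted orthogonal scores", {
  d <- sim_latent_data(N = 40, P = 50, n_pred = 1, n_orth = 1, seed = 11)
  m <- pls2(d$X, d$Y, ncomp = 2)
  pt <- post_transform(m)
  expect_equal(pt$Ap, 1)
  expect_equal(pt$Ao, 1)
  expect_gt(abs(cor(pt$To[, 1], d$truth$To[, 1])), 0.95)
  expect_lt(max(abs(crossprod(m$y, pt$To))), 1e-8)
})

test_that("multi-response predictive rank equals rank(Y'XW) and To is Y-orthogonal", {
  set.seed(77)
  d <- sim_latent_data(N = 40, P = 30, M = 2, n_pred = 2, n_orth = 2,
                       seed = 77)
  m <- pls2(d$X, d$Y, ncomp = 4)
  pt <- post_transform(m)
  rk <- qr(crossprod(m$y, m$x %*% m$weights))$rank
  expect_equal(pt$Ap, rk)
  expect_equal(pt$Ap, 2)
  expect_equal(pt$Ao, 2)
  expect_lt(max(abs(crossprod(m$y, pt$To))), 1e-8)
  expect_lt(max(abs(crossprod(pt$Tp, pt$To))), 1e-8)
  # decomposition identity against the parent residuals
  expect_lt(max(abs(m$x - tcrossprod(pt$Tp, pt$Pp) -
                      tcrossprod(pt$To, pt$Po) - m$residuals$X)), 1e-8)
  expect_lt(max(abs(m$y - tcrossprod(pt$Tp, pt$Qp) - m$residuals$Y)), 1e-8)
  expect_lt(max(abs(crossprod(pt$G) - diag(4))), 1e-8)
  expect_lt(max(abs(pt$model$coefficients - m$coefficients)), 1e-10)
})

test_that("post-transformation preserves R2 and cross-validated Q2", {
  d <- sim_latent_data(N = 30, P = 12, n_pred = 1, n_orth = 1, seed = 23)
  m <- pls2(d$X, d$Y, ncomp = 2)
  pt <- post_transform(m)
  expect_equal(r_squared(pt$model), r_squared(m), tolerance = 1e-10)
  folds <- make_folds(30, 7, seed = 1)
  q2_parent <- cv_q2(m, folds = folds)$q2
  press_pt <- ss_pt <- 0
  Yt <- d$Y
  for (f in sort(unique(folds))) {
    test <- which(folds == f); train <- which(folds != f)
    mf <- pls2(d$X[train, ], d$Y[train, , drop = FALSE], ncomp = 2)
    ptf <- post_transform(mf)
    yhat <- predict(ptf, d$X[test, , drop = FALSE])
    press_pt <- press_pt + sum((Yt[test, ] - yhat)^2)
    ss_pt <- ss_pt + sum((Yt[test, ] - mean(Yt[train, ]))^2)
  }
  expect_equal(unname(1 - press_pt / ss_pt), unname(q2_parent),
               tolerance = 1e-10)
})

test_that("single-response predictive component reproduces full-model predictions", {
  d <- sim_latent_data(N = 30, P = 15, n_pred = 1, n_orth = 2, seed = 29)
  m <- pls2(d$X, d$Y, ncomp = 3)
  pt <- post_transform(m)
  expect_equal(pt$Ap, 1)
  expect_lt(max(abs(predict(pt) - predict(m))), 1e-8)
})

test_that("split VIP scores separate predictive from structured-noise variables", {
  d <- sim_latent_data(N = 40, P = 50, n_pred = 1, n_orth = 1, seed = 11)
  m <- pls2(d$X, d$Y, ncomp = 2)
  pt <- post_transform(m)
  pv <- predictive_vip(pt)
  expect_equal(mean(pv$vip_p^2), 1, tolerance = 1e-8)
  expect_equal(mean(pv$vip_o^2), 1, tolerance = 1e-8)
  orth_vars <- d$truth$orth_vars
  # every structured-noise variable sits above the VIP rule-of-thumb on the
  # orthogonal score and below it on the predictive score
  expect_true(all(pv$vip_o[orth_vars] > 1))
  expect_true(all(pv$vip_p[orth_vars] < 1))
})

test_that("with no orthogonal block the split VIP collapses to the classic VIP", {
  set.seed(17)
  X <- matrix(rnorm(20 * 6), 20, 6)
  Y <- matrix(rnorm(20 * 2), 20, 2)
  m <- pls2(X, Y, ncomp = 2)
  pt <- post_transform(m)
  expect_equal(pt$Ao, 0)
  pv <- predictive_vip(pt)
  expect_true(attr(pv, "no_orthogonal"))
  expect_true(all(pv$vip_o == 0))
  expect_equal(pv$vip_p, vip(m)$vip, tolerance = 1e-8)
})
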