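test_that("weight extraction finds single-direction covariance exactly", {
  set.seed(1)
  f <- rnorm(12)
  E <- matrix(0, 12, 5)
  E[, 3] <- f
  F <- matrix(f, 12, 1)
  res <- compute_weight(E, F)
  expect_equal(res$w, c(0, 0, 1, 0, 0))
  expect_equal(res$lambda, sum(crossprod(E, F)^2))
})

test_that("null cross-covariance signals no remaining covariance", {
  E <- cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  F <- matrix(c(1, 1, 1, 1), 4, 1)  # orthogonal to both columns
  expect_error(compute_weight(E, F), "no remaining covariance")
})

test_that("weight equals the dominant eigenvector of EtFFtE (full-eigen oracle)", {
  E <- centred_random(12, 6, seed = 42)
  F <- centred_random(12, 2, seed = 43)
  res <- compute_weight(E, F)
  M <- crossprod(E, F)
  eg <- eigen(M %*% t(M), symmetric = TRUE)
  w_or <- eg$vectors[, 1]
  if (sum(w_or * res$w) < 0) w_or <- -w_or
  expect_equal(res$w, w_or, tolerance = 1e-10)
  expect_equal(res$lambda, eg$values[1], tolerance = 1e-10)
})

test_that("single centred column regressed on itself gives B = 1", {
  x <- matrix(rnorm(15), 15, 1)
  m <- pls2(x, x, ncomp = 1)
  expect_equal(unname(coef(m)[1, 1]), 1)
})

test_that("all decomposition invariants hold on seeded random fits", {
  for (seed in c(2, 7, 19)) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 8), 20, 8)
    Y <- matrix(rnorm(20 * 2), 20, 2)
    m <- pls2(X, Y, ncomp = 3)
    A <- m$ncomp
    TtT <- crossprod(m$scores)
    expect_lt(max(abs(TtT - diag(diag(TtT)))), 1e-8)
    expect_lt(max(abs(crossprod(m$weights) - diag(A))), 1e-8)
    PtW <- crossprod(m$x_loadings, m$weights)
    expect_lt(max(abs(PtW[lower.tri(PtW)])), 1e-8)
    expect_equal(det(PtW), 1, tolerance = 1e-6)
    expect_lt(max(abs(m$scores - m$x %*% m$Wstar)), 1e-8)
    expect_lt(max(abs(m$x - tcrossprod(m$scores, m$x_loadings) -
                        m$residuals$X)), 1e-8)
    expect_lt(max(abs(m$y - tcrossprod(m$scores, m$y_loadings) -
                        m$residuals$Y)), 1e-8)
    expect_true(all(diff(m$eigvals) <= 1e-8) && all(m$eigvals >= 0))
    # closed-form B in terms of W equals the iteratively computed one
    B2 <- m$weights %*%
      solve(crossprod(m$weights, crossprod(m$x) %*% m$weights)) %*%
      crossprod(m$weights, crossprod(m$x, m$y))
    expect_lt(max(abs(B2 - m$coefficients)), 1e-8)
  }
})

test_that("orthogonal-design OLS limit is reached at A = P", {
  X <- factorial_design(3, reps = 3)
  set.seed(5)
  Y <- X %*% matrix(rnorm(6), 3, 2) + matrix(rnorm(nrow(X) * 2), ncol = 2)
  m <- suppressWarnings(pls2(X, Y, ncomp = 3))
  Yc <- scale(Y, scale = FALSE)
  expect_lt(max(abs(m$coefficients - ols_coef(X, Yc))), 1e-8)
})

test_that("eigenvalue algorithm matches the iterative NIPALS oracle", {
  set.seed(11)
  X <- scale(matrix(rnorm(20 * 8), 20, 8), scale = FALSE)
  Y <- scale(matrix(rnorm(20 * 2), 20, 2), scale = FALSE)
  m <- pls2(X, Y, ncomp = 3, center = FALSE)
  or <- nipals_pls2(X, Y, 3)
  expect_lt(max(abs(m$coefficients - or$B)), 1e-7)
  expect_lt(max(abs(m$scores - align_signs(m$scores, or$T))), 1e-7)
  expect_lt(max(abs(m$x_loadings - align_signs(m$x_loadings, or$P))), 1e-7)
  q_aligned <- sweep(or$Q, 2, sign(colSums(m$scores * align_signs(m$scores, or$T))), "*")
  expect_lt(max(abs(tcrossprod(m$scores, m$y_loadings) -
                      tcrossprod(or$T, or$Q))), 1e-7)
})

test_that("fitted values, centred-origin prediction and new-data predictions behave", {
  set.seed(3)
  X <- matrix(rnorm(18 * 6), 18, 6)
  Y <- matrix(rnorm(18 * 2), 18, 2)
  m <- pls2(X, Y, ncomp = 2)
  expect_equal(predict(m), fitted(m))
  expect_equal(predict(m),
               sweep(tcrossprod(m$scores, m$y_loadings), 2,
                     colMeans(Y), "+"), ignore_attr = TRUE)
  # the training-mean row is the centred origin: prediction = Y mean
  origin <- matrix(colMeans(X), 1)
  expect_equal(drop(predict(m, origin)), colMeans(Y), ignore_attr = TRUE)
  # OLS-limit model predicts like the least-squares oracle on new rows
  Xf <- factorial_design(3, reps = 3)
  set.seed(8)
  Yf <- Xf %*% matrix(rnorm(3), 3, 1) + rnorm(nrow(Xf))
  mo <- suppressWarnings(pls2(Xf, Yf, ncomp = 3))
  Xnew <- matrix(rnorm(12), 4, 3)
  pred_ols <- Xnew %*% ols_coef(Xf, scale(Yf, scale = FALSE)) + mean(Yf)
  expect_lt(max(abs(predict(mo, Xnew) - pred_ols)), 1e-8)
})

test_that("explained variance fractions are exact and match the reconstruction oracle", {
  d <- sim_latent_data(N = 25, P = 10, n_pred = 1, n_orth = 0,
                       noise_sd = 0, seed = 21)
  m1 <- pls2(d$X, d$Y, ncomp = 1)
  ev1 <- explained_variance(m1)
  expect_equal(unname(ev1$table["Y", 1]), 1, tolerance = 1e-8)

  set.seed(9)
  X <- matrix(rnorm(20 * 8), 20, 8); Y <- matrix(rnorm(20 * 2), 20, 2)
  m <- pls2(X, Y, ncomp = 3)
  ev <- explained_variance(m)
  expect_equal(sum(ev$ssy) + sum(m$residuals$Y^2), sum(m$y^2),
               tolerance = 1e-8)
  expect_equal(sum(ev$ssx) + sum(m$residuals$X^2), sum(m$x^2),
               tolerance = 1e-8)
  # brute-force reconstruction norms per component
  for (j in seq_len(m$ncomp)) {
    expect_equal(ev$ssy[j],
                 sum(tcrossprod(m$scores[, j], m$y_loadings[, j])^2),
                 tolerance = 1e-8)
    expect_equal(ev$ssx[j],
                 sum(tcrossprod(m$scores[, j], m$x_loadings[, j])^2),
                 tolerance = 1e-8)
  }
})

test_that("R2 is non-decreasing in the number of components", {
  set.seed(13)
  X <- matrix(rnorm(24 * 10), 24, 10)
  Y <- matrix(rnorm(24 * 2), 24, 2)
  m <- pls2(X, Y, ncomp = 6)
  r2_by_a <- sapply(seq_len(m$ncomp), function(a) {
    res <- m$y - tcrossprod(m$scores[, seq_len(a), drop = FALSE],
                            m$y_loadings[, seq_len(a), drop = FALSE])
    1 - colSums(res^2) / colSums(m$y^2)
  })
  expect_true(all(diff(t(r2_by_a)) >= -1e-12))
})

test_that("x- and y-scores are collinear on noise-free linear data", {
  d <- sim_latent_data(N = 30, P = 12, n_pred = 1, n_orth = 0,
                       noise_sd = 0, seed = 31)
  m <- pls2(d$X, d$Y, ncomp = 1)
  expect_gt(cor(m$scores[, 1], m$y_scores[, 1]), 0.999)
})

test_that("degenerate covariance truncates with a warning and non-centred input errors", {
  d <- sim_latent_data(N = 20, P = 6, n_pred = 1, n_orth = 0, noise_sd = 0,
                       seed = 41)
  expect_warning(m <- pls2(d$X, d$Y, ncomp = 5), "truncated")
  expect_lt(m$ncomp, 5)
  expect_match(m$meta$warnings, "truncated")
  set.seed(4)
  Xo <- matrix(rnorm(30), 10, 3) + 5
  expect_error(pls2(Xo, rnorm(10), ncomp = 1, center = FALSE), "X-block")
  expect_error(pls2(scale(Xo, scale = FALSE), rnorm(10) + 3, ncomp = 1,
                    center = FALSE), "Y-block")
})
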