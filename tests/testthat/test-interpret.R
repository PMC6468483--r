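test_that("VIP is 1 for a symmetric two-variable single-component model", {
  set.seed(1)
  t0 <- rnorm(20)
  X <- cbind(t0, t0) + matrix(rnorm(40, sd = 1e-8), 20, 2)
  y <- t0 + rnorm(20, sd = 0.1)
  m <- pls2(X, y, ncomp = 1)
  expect_equal(vip(m)$vip, c(1, 1), tolerance = 1e-4)
})

test_that("VIP matches a term-by-term evaluation of the formula and has unit mean square", {
  set.seed(20)
  X <- matrix(rnorm(20 * 8), 20, 8)
  Y <- matrix(rnorm(20 * 2), 20, 2)
  m <- pls2(X, Y, ncomp = 3)
  v <- vip(m)$vip
  expect_equal(mean(v^2), 1, tolerance = 1e-8)
  # brute-force formula oracle
  ssy_j <- sapply(seq_len(3), function(j)
    sum(m$scores[, j]^2) * sum(m$y_loadings[, j]^2))
  v_or <- sapply(seq_len(8), function(i)
    sqrt(8 * sum(m$weights[i, ]^2 * ssy_j) / sum(ssy_j)))
  expect_equal(v, v_or, tolerance = 1e-10)
})

test_that("selectivity-ratio threshold matches the F-quantile table", {
  expect_equal(round(sr_threshold(0.05, 38), 2), 1.75)
  expect_equal(sr_threshold(0.05, 38), qf(0.95, 36, 35))
})

test_that("selectivity ratio selects exactly the variables carrying the predictive direction", {
  d <- sim_latent_data(N = 38, P = 40, n_pred = 1, n_orth = 0,
                       loading_sparsity = 3 / 40, seed = 6)
  expect_equal(sum(d$truth$informative), 3)
  m <- pls2(d$X, d$Y, ncomp = 1)
  pt <- post_transform(m)
  sr <- selectivity_ratio(pt, alpha = 0.05)
  expect_equal(which(sr$selected), which(d$truth$informative))
  expect_equal(attr(sr, "threshold"), qf(0.95, 36, 35))
})

test_that("selectivity ratio requires a single predictive component and zero loading gives zero SR", {
  d <- sim_latent_data(N = 30, P = 20, M = 2, n_pred = 2, n_orth = 0,
                       seed = 8)
  m <- pls2(d$X, d$Y, ncomp = 2)
  pt <- post_transform(m)
  expect_equal(pt$Ap, 2)
  expect_error(selectivity_ratio(pt), "single predictive")
  # a variable with zero predictive loading has SR 0
  d1 <- sim_latent_data(N = 20, P = 10, n_pred = 1, n_orth = 0,
                        noise_sd = 0, loading_sparsity = 0.5, seed = 9)
  m1 <- pls2(d1$X, d1$Y, ncomp = 1)
  pt1 <- post_transform(m1)
  sr1 <- selectivity_ratio(pt1)
  zero_vars <- which(!d1$truth$informative)
  expect_true(all(sr1$sr[zero_vars] < 1e-10))
})

test_that("adding pure noise to a variable decreases its selectivity ratio", {
  d <- sim_latent_data(N = 30, P = 15, n_pred = 1, n_orth = 0, seed = 10)
  m <- pls2(d$X, d$Y, ncomp = 1)
  sr0 <- selectivity_ratio(post_transform(m))$sr
  j <- which.max(sr0)
  X2 <- d$X
  set.seed(11)
  X2[, j] <- X2[, j] + rnorm(30, sd = 2)
  sr1 <- selectivity_ratio(post_transform(pls2(X2, d$Y, ncomp = 1)))$sr
  expect_lt(sr1[j], sr0[j])
})

test_that("correlation loadings match a direct Pearson oracle and handle special cases", {
  set.seed(12)
  X <- matrix(rnorm(20 * 5), 20, 5)
  Y <- matrix(rnorm(20), ncol = 1)
  m <- pls2(X, Y, ncomp = 2)
  cl <- correlation_loadings(m)
  for (j in 1:2) {
    expect_equal(cl[1:5, j], cor(m$x, m$scores[, j])[, 1],
                 ignore_attr = TRUE)
    expect_equal(cl[6, j], cor(m$y[, 1], m$scores[, j]),
                 ignore_attr = TRUE)
  }
  expect_true(all(abs(cl) <= 1 + 1e-12))
  # a variable equal to the first score correlates perfectly
  X2 <- cbind(m$scores[, 1], X)
  m2 <- pls2(X2, Y, ncomp = 2)
  cl2 <- correlation_loadings(m2)
  expect_equal(abs(cl2[1, 1]), 1, tolerance = 1e-6)
  # noise-free rank-1 data: every carrying variable correlates at |1|
  d <- sim_latent_data(N = 15, P = 6, n_pred = 1, n_orth = 0, noise_sd = 0,
                       loading_sparsity = 0.5, seed = 13)
  m3 <- pls2(d$X, d$Y, ncomp = 1)
  cl3 <- correlation_loadings(m3)
  expect_equal(abs(cl3[which(d$truth$informative), 1]),
               rep(1, 3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(any(attr(cl3, "constant")[which(!d$truth$informative)]))
})

test_that("w*q coordinates reproduce the regression coefficients", {
  set.seed(14)
  X <- matrix(rnorm(20 * 6), 20, 6)
  Y <- matrix(rnorm(20 * 2), 20, 2)
  m <- pls2(X, Y, ncomp = 2)
  expect_lt(max(abs(m$Wstar %*% t(m$y_loadings) - m$coefficients)), 1e-10)
  wq <- wq_coordinates(m)
  expect_equal(nrow(wq), 8)
  expect_setequal(wq$role, c("variable", "response"))
  # scalar case: coordinate times q equals the coefficient
  m1 <- pls2(X, Y[, 1], ncomp = 1)
  wq1 <- wq_coordinates(m1)
  b1 <- wq1$comp1[wq1$role == "variable"] * wq1$comp1[wq1$role == "response"]
  expect_equal(b1, unname(coef(m1)[, 1]), tolerance = 1e-10)
  m4 <- pls2(X, Y, ncomp = 4)
  expect_warning(wq_coordinates(m4), "two or three")
})
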