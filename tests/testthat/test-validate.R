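test_that("fold assignment is a deterministic near-equal partition", {
  f1 <- make_folds(23, 7, seed = 5)
  f2 <- make_folds(23, 7, seed = 5)
  expect_identical(f1, f2)
  expect_true(all(range(tabulate(f1)) %in% 3:4))
  expect_equal(make_folds(10, 3, type = "venetian"),
               rep_len(1:3, 10))
  expect_error(make_folds(5, 6), "between 2 and N")
})

test_that("Q2 is high on learnable signal and low after response permutation", {
  d <- sim_latent_data(N = 30, P = 12, n_pred = 1, n_orth = 0,
                       noise_sd = 0.05, seed = 3)
  m <- pls2(d$X, d$Y, ncomp = 1)
  expect_gt(cv_q2(m, k = 7, seed = 1)$q2, 0.99)
  set.seed(4)
  yperm <- d$Y[sample(30), , drop = FALSE]
  mp <- pls2(d$X, yperm, ncomp = 1)
  expect_lt(cv_q2(mp, k = 7, seed = 1)$q2, 0.2)
})

test_that("two-fold PRESS matches a manual computation", {
  set.seed(6)
  X <- matrix(rnorm(6 * 3), 6, 3)
  Y <- matrix(rnorm(6), ncol = 1)
  m <- pls2(X, Y, ncomp = 1)
  folds <- c(1, 1, 1, 2, 2, 2)
  cv <- cv_q2(m, folds = folds)
  press_manual <- 0
  ss_manual <- 0
  for (f in 1:2) {
    tr <- which(folds != f); te <- which(folds == f)
    mf <- pls2(X[tr, ], Y[tr, , drop = FALSE], ncomp = 1)
    press_manual <- press_manual +
      sum((Y[te, ] - predict(mf, X[te, , drop = FALSE]))^2)
    ss_manual <- ss_manual + sum((Y[te, ] - mean(Y[tr, ]))^2)
  }
  expect_equal(unname(cv$press), press_manual, tolerance = 1e-12)
  expect_equal(unname(cv$ss), ss_manual, tolerance = 1e-12)
  expect_equal(unname(cv$q2), 1 - press_manual / ss_manual)
})

test_that("strong signal attains the minimum permutation p-value", {
  d <- sim_latent_data(N = 24, P = 8, n_pred = 1, n_orth = 0,
                       noise_sd = 0.05, seed = 7)
  m <- pls2(d$X, d$Y, ncomp = 1)
  pt <- permutation_test(m, n_perm = 99, seed = 2, k = 5)
  expect_equal(unname(pt$p["q2"]), 1 / 100)
  expect_equal(unname(pt$p["r2"]), 1 / 100)
})

test_that("exhaustive permutation p-value matches full enumeration at N = 4", {
  set.seed(8)
  X <- matrix(rnorm(4 * 3), 4, 3)
  Y <- matrix(rnorm(4), ncol = 1)
  m <- pls2(X, Y, ncomp = 1)
  perms <- all_permutations(4)
  pt <- permutation_test(m, permutations = perms, k = 2, seed = 1,
                         statistics = "r2")
  # oracle: refit per permutation with the independent NIPALS implementation
  r2_null <- apply(perms, 1, function(pr) {
    Xc <- scale(X, scale = FALSE)
    Yc <- scale(Y[pr, , drop = FALSE], scale = FALSE)
    or <- nipals_pls2(Xc, Yc, 1)
    1 - sum((Yc - tcrossprod(or$T, or$Q))^2) / sum(Yc^2)
  })
  obs <- 1 - sum((scale(Y, scale = FALSE) -
                    tcrossprod(m$scores, m$y_loadings))^2) /
    sum(scale(Y, scale = FALSE)^2)
  p_or <- (sum(r2_null >= obs) + 1) / (nrow(perms) + 1)
  expect_equal(unname(pt$p["r2"]), p_or)
})

test_that("null-data p-values are conservative and roughly uniform", {
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    X <- matrix(rnorm(20 * 6), 20, 6)
    Y <- matrix(rnorm(20), ncol = 1)
    m <- pls2(X, Y, ncomp = 1)
    pt <- permutation_test(m, n_perm = 19, seed = s, statistics = "r2")
    expect_gte(pt$p["r2"], 1 / 20)
    if (pt$p["r2"] > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("component selection recovers planted dimensionality and fails on noise", {
  d <- sim_latent_data(N = 36, P = 15, M = 1, n_pred = 2, n_orth = 0,
                       noise_sd = 0.2, seed = 9)
  sel <- select_ncomp(d$X, d$Y, ncomp_max = 5, n_perm = 49, seed = 1)
  expect_equal(sel$chosen_A, 2)
  expect_equal(sel$status, "ok")
  set.seed(10)
  Xn <- matrix(rnorm(20 * 8), 20, 8)
  Yn <- matrix(rnorm(20), ncol = 1)
  seln <- select_ncomp(Xn, Yn, ncomp_max = 3, n_perm = 49, seed = 1)
  expect_true(is.na(seln$chosen_A))
  expect_match(seln$status, "failure")
})

test_that("error metrics are exact and honour the response-transform contract", {
  expect_equal(unname(error_metrics(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(unname(error_metrics(c(0, 2), c(1, 1), "prediction")), 1)
  expect_named(error_metrics(1, 1, "calculation"), "SDEC")
  expect_error(error_metrics(1:3, 1:2), "length")
  # sqrt-transformed response: predictions and errors in original units
  d <- sim_latent_data(N = 30, P = 10, n_pred = 1, n_orth = 0,
                       noise_sd = 0.05, seed = 11)
  y_min <- (d$Y - min(d$Y) + 0.5)^2   # positive, "minutes"-like
  m <- pls2(d$X, y_min, ncomp = 1, y_transform = "sqrt")
  pr <- predict(m)
  sdec <- error_metrics(y_min, pr, "calculation")
  # back-transformation really happened: fitted values live on the y scale
  expect_lt(sdec, stats::sd(y_min))
  expect_gt(cor(pr[, 1], y_min[, 1]), 0.99)
  # the model is fitted on the square-root scale
  expect_equal(m$y[, 1], drop(sqrt(y_min) - mean(sqrt(y_min))),
               ignore_attr = TRUE)
})

test_that("stratified split hits requested sizes, is deterministic, covers strata", {
  set.seed(12)
  y <- rnorm(59)
  sp <- stratified_split(y, 38 / 59, n_strata = 5, seed = 2)
  expect_equal(length(sp$train), 38)
  expect_equal(length(sp$test), 21)
  expect_setequal(c(sp$train, sp$test), 1:59)
  sp2 <- stratified_split(y, 38 / 59, n_strata = 5, seed = 2)
  expect_identical(sp, sp2)
  expect_equal(stratified_split(y, 1)$train, 1:59)
  # both sets span the response range reasonably
  expect_lt(abs(mean(y[sp$train]) - mean(y[sp$test])), 1)
})

test_that("fold pre-treatment parameters ignore held-out samples (no leakage)", {
  set.seed(13)
  X <- matrix(rnorm(21 * 5), 21, 5)
  Y <- matrix(rnorm(21), ncol = 1)
  folds <- make_folds(21, 7, seed = 1)
  m1 <- pls2(X, Y, ncomp = 1)
  cv1 <- cv_q2(m1, folds = folds)
  f <- folds[1]  # sample 1 is held out in fold f
  X2 <- X
  X2[1, ] <- X2[1, ] + 1000  # gross outlier, only ever in fold f's test set
  m2 <- pls2(X2, Y, ncomp = 1)
  cv2 <- cv_q2(m2, folds = folds)
  expect_equal(cv1$fold_centers[[as.character(f)]],
               cv2$fold_centers[[as.character(f)]])
  # out-of-fold predictions for fold f's other samples are also unchanged
  others <- setdiff(which(folds == f), 1)
  expect_equal(cv1$predictions[others, ], cv2$predictions[others, ])
})
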