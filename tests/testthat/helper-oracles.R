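# Independent oracles used to cross-check the package implementation.
# They deliberately use different algorithms (iterative NIPALS, explicit
# eigendecompositions, ordinary least squares) from the SVD-based engine.

# classic iterative NIPALS-PLS2 with power-method inner loop
nipals_pls2 <- function(X, Y, A, tol = 1e-13, maxit = 1000) {
  E <- X; Fr <- Y
  N <- nrow(X); P <- ncol(X); M <- ncol(Y)
  W <- matrix(0, P, A); Tm <- matrix(0, N, A); Q <- matrix(0, M, A)
  for (a in seq_len(A)) {
    u <- Fr[, which.max(colSums(Fr^2))]
    t_old <- rep(0, N)
    for (it in seq_len(maxit)) {
      w <- drop(crossprod(E, u)); w <- w / sqrt(sum(w^2))
      t_a <- drop(E %*% w)
      q <- drop(crossprod(Fr, t_a)) / sum(t_a^2)
      u <- drop(Fr %*% q) / sum(q^2)
      if (sqrt(sum((t_a - t_old)^2)) < tol * sqrt(sum(t_a^2))) break
      t_old <- t_a
    }
    p <- drop(crossprod(E, t_a)) / sum(t_a^2)
    E <- E - tcrossprod(t_a, p)
    Fr <- Fr - tcrossprod(t_a, q)
    W[, a] <- w; Tm[, a] <- t_a; Q[, a] <- q
  }
  Pl <- sweep(crossprod(X, Tm), 2, colSums(Tm^2), "/")
  Wstar <- W %*% solve(crossprod(Pl, W))
  list(W = W, T = Tm, P = Pl, Q = Q, B = Wstar %*% t(Q))
}

ols_coef <- function(X, Y) solve(crossprod(X), crossprod(X, Y))

# align oracle component signs to a reference (scores/weights are
# sign-conventional)
align_signs <- function(ref, other) {
  s <- sign(colSums(ref * other))
  s[s == 0] <- 1
  sweep(other, 2, s, "*")
}

centred_random <- function(N, P, seed) {
  set.seed(seed)
  scale(matrix(rnorm(N * P), N, P), center = TRUE, scale = FALSE)
}

# balanced full-factorial design: mutually orthogonal, mean-centred columns
factorial_design <- function(p, reps = 2) {
  X <- as.matrix(expand.grid(rep(list(c(-1, 1)), p)))
  X <- X[rep(seq_len(nrow(X)), reps), , drop = FALSE]
  dimnames(X) <- NULL
  X
}

# explicit feature map of the degree-2 polynomial kernel (x'y + c)^2
poly2_features <- function(X, offset) {
  P <- ncol(X)
  sq <- X^2
  cross <- NULL
  if (P > 1) {
    idx <- utils::combn(P, 2)
    cross <- sqrt(2) * X[, idx[1, ], drop = FALSE] * X[, idx[2, ], drop = FALSE]
  }
  cbind(sq, cross, sqrt(2 * offset) * X, sqrt(offset^2) * rep(1, nrow(X)))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub), n - 1))
  }))
}
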