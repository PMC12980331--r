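test_that("soft threshold matches its closed form and is non-expansive", {
  expect_equal(soft_threshold(1.2, 0.5), 0.7)
  expect_equal(soft_threshold(-0.3, 0.5), 0)
  A <- matrix(c(-2, 0.1, 3, -0.4), 2, 2)
  expect_equal(soft_threshold(A, 0), A)
  expect_error(soft_threshold(A, -1), "negative")
  expect_error(soft_threshold(A, matrix(0.1, 3, 3)), "shape")

  # elementwise closed form on random input, matrix threshold
  set.seed(1)
  B <- matrix(rnorm(20), 4, 5)
  Tau <- matrix(runif(20), 4, 5)
  manual <- mapply(function(a, t) sign(a) * max(abs(a) - t, 0), B, Tau)
  expect_equal(as.numeric(soft_threshold(B, Tau)), manual)

  # non-expansiveness: |S_t(a) - S_t(b)| <= |a - b| elementwise
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10); tau <- runif(1)
    expect_true(all(abs(soft_threshold(a, tau) - soft_threshold(b, tau)) <=
                      abs(a - b) + 1e-15))
  }
})

test_that("embedding distances equal the pairwise definition", {
  F2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(embedding_distance(F2), rbind(c(0, 1), c(1, 0)), ignore_attr = TRUE)
  expect_equal(embedding_distance(matrix(3, 4, 2)), matrix(0, 4, 4), ignore_attr = TRUE)

  set.seed(2)
  F5 <- matrix(rnorm(15), 5, 3)
  D <- embedding_distance(F5)
  brute <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) brute[i, j] <- 0.5 * sum((F5[i, ] - F5[j, ])^2)
  expect_equal(D, brute, ignore_attr = TRUE)
  expect_equal(D, t(D), ignore_attr = TRUE)
  expect_true(all(diag(D) == 0))
})

test_that("Z update shrinks against the combined threshold and zeroes the diagonal", {
  n <- 4
  st <- seomlr:::selfrep_state(3, n, mu0 = 2)
  D <- matrix(0, n, n)
  # C = Q2 = 0: shrinkage of zero is zero
  expect_equal(seomlr:::update_Z(st, matrix(0, n, n), D, 1, 1, 1), matrix(0, n, n))

  # zero thresholds, C = I: identity survives shrinkage, then diagonal removed
  st$C <- diag(n)
  expect_equal(seomlr:::update_Z(st, matrix(0, n, n), D, 0, 0, 0), matrix(0, n, n))

  # random instance vs scalar-by-scalar evaluation of the update rule
  set.seed(3)
  st$C <- matrix(rnorm(n * n), n, n)
  st$Q2 <- matrix(rnorm(n * n), n, n)
  st$mu <- 1.7
  other <- matrix(abs(rnorm(n * n)), n, n)
  Df <- embedding_distance(matrix(rnorm(n * 2), n, 2))
  xi <- c(0.3, 0.5, 0.2)
  Z <- seomlr:::update_Z(st, other, Df, xi[1], xi[2], xi[3])
  manual <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    a <- st$C[i, j] + st$Q2[i, j] / st$mu
    tau <- (xi[1] + xi[2] * other[i, j] + xi[3] * Df[i, j]) / st$mu
    manual[i, j] <- sign(a) * max(abs(a) - tau, 0)
  }
  diag(manual) <- 0
  expect_equal(Z, manual)
  expect_true(all(diag(Z) == 0))
})

test_that("E update is shrinkage of the representation residual", {
  set.seed(4)
  d <- 3; n <- 5
  X <- matrix(rnorm(d * n), d, n)
  st <- seomlr:::selfrep_state(d, n, mu0 = 2)

  # exact representation, zero dual: no error absorbed
  st$C <- diag(n)
  expect_equal(seomlr:::update_E(st, X, X %*% st$C), matrix(0, d, n))

  # large mu: threshold vanishes, E -> X - XC + Q1/mu
  st$C <- matrix(rnorm(n * n), n, n)
  st$Q1 <- matrix(rnorm(d * n), d, n)
  st$mu <- 1e9
  XC <- X %*% st$C
  expect_equal(seomlr:::update_E(st, X, XC), X - XC + st$Q1 / st$mu,
               tolerance = 1e-6)

  # random instance vs elementwise formula
  st$mu <- 0.9
  E <- seomlr:::update_E(st, X, XC)
  A <- X - XC + st$Q1 / st$mu
  expect_equal(E, sign(A) * pmax(abs(A) - 1 / st$mu, 0))
})

test_that("C update solves its normal equations", {
  set.seed(5)
  d <- 4; n <- 5
  X <- matrix(rnorm(d * n), d, n)
  st <- seomlr:::selfrep_state(d, n, mu0 = 0.5)
  st$Z <- matrix(rnorm(n * n), n, n); diag(st$Z) <- 0
  st$E <- matrix(rnorm(d * n), d, n)
  st$Q1 <- matrix(rnorm(d * n), d, n)
  st$Q2 <- matrix(rnorm(n * n), n, n)
  fac <- chol(crossprod(X) + diag(n))
  C <- seomlr:::update_C(st, X, fac)

  rhs <- crossprod(X, X - st$E + st$Q1 / st$mu) + st$Z - st$Q2 / st$mu
  expect_lt(max(abs((crossprod(X) + diag(n)) %*% C - rhs)), 1e-8)
  # dense-inverse oracle
  expect_equal(C, solve(crossprod(X) + diag(n)) %*% rhs, tolerance = 1e-10)

  # X = 0: identity system
  X0 <- matrix(0, d, n)
  C0 <- seomlr:::update_C(st, X0, chol(diag(n)))
  expect_equal(C0, st$Z - st$Q2 / st$mu)
})

test_that("dual updates accumulate residuals and grow mu geometrically", {
  set.seed(6)
  d <- 3; n <- 4
  X <- matrix(rnorm(d * n), d, n)
  st <- seomlr:::selfrep_state(d, n, mu0 = 0.1)
  # feasible point: X = XC + E and C = Z leave the duals unchanged
  st$C <- diag(n) * 0; st$Z <- st$C
  st$E <- X
  st2 <- seomlr:::update_duals(st, X, X %*% st$C, rho = 1.2, mu_max = 1e8)
  expect_equal(st2$Q1, st$Q1)
  expect_equal(st2$Q2, st$Q2)

  # mu sequence 0.1, 0.12, 0.144, ... capped at mu_max
  mus <- numeric(4); s <- st
  for (k in 1:4) {
    s <- seomlr:::update_duals(s, X, X %*% s$C, rho = 1.2, mu_max = 1e8)
    mus[k] <- s$mu
  }
  expect_equal(mus, 0.1 * 1.2^(1:4))
  s$mu <- 9e7
  s <- seomlr:::update_duals(s, X, X %*% s$C, rho = 1.2, mu_max = 1e8)
  expect_equal(s$mu, 1e8)
  s <- seomlr:::update_duals(s, X, X %*% s$C, rho = 1.2, mu_max = 1e8)
  expect_equal(s$mu, 1e8)
})

test_that("ADMM solves the self-representation subproblem", {
  n <- 20
  zero <- matrix(0, n, n)

  # trivial fixed point
  X0 <- matrix(0, 5, n)
  st <- seomlr:::selfrep_state(5, n, 0.1)
  out <- seomlr:::admm_solve(X0, st, zero, zero, 1, 0, 0, T1 = 30L, eps = 2e-4)
  expect_equal(out$Z, zero)
  expect_equal(out$E, matrix(0, 5, n))
  expect_equal(out$n_iter, 1L)

  # two-cluster toy: the constraint residual decays with the penalty schedule
  # (about 1e-2 after 30 sweeps) and reaches the 2e-4 tolerance within 60
  set.seed(1)
  X <- cbind(matrix(rnorm(5 * 10, 3), 5, 10), matrix(rnorm(5 * 10, -3), 5, 10))
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  st <- seomlr:::selfrep_state(5, n, 0.1)
  out30 <- seomlr:::admm_solve(X, st, zero, zero, 1, 0, 0, T1 = 30L, eps = 2e-4)
  expect_lt(out30$residual, 0.05)
  out60 <- seomlr:::admm_solve(X, seomlr:::selfrep_state(5, n, 0.1),
                               zero, zero, 1, 0, 0, T1 = 60L, eps = 2e-4)
  expect_lt(out60$residual, 2e-4)
  expect_lt(out60$n_iter, 60L)  # exited on the residual rule, not the cap
  expect_true(all(diag(out60$Z) == 0))
})

test_that("noiseless two-subspace data yields block-structured Z", {
  set.seed(2)
  B1 <- qr.Q(qr(matrix(rnorm(10 * 2), 10, 2)))
  B2 <- qr.Q(qr(matrix(rnorm(10 * 2), 10, 2)))
  X <- cbind(B1 %*% matrix(rnorm(2 * 12), 2, 12),
             B2 %*% matrix(rnorm(2 * 12), 2, 12))
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  n <- 24
  zero <- matrix(0, n, n)
  out <- seomlr:::admm_solve(X, seomlr:::selfrep_state(10, n, 0.1),
                             zero, zero, 0.1, 0, 0, T1 = 100L, eps = 2e-4)
  Z <- abs(out$Z)
  gl <- rep(1:2, each = 12)
  between <- sum(Z[outer(gl, gl, "!=")]) / sum(Z)
  expect_lt(between, 0.2)
})

test_that("exclusivity coupling suppresses overlapping support across views", {
  set.seed(3)
  n <- 15
  X <- matrix(rnorm(6 * n), 6, n)
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  zero <- matrix(0, n, n)
  D <- zero

  overlap <- function(xi2) {
    s1 <- seomlr:::selfrep_state(6, n, 0.1)
    s2 <- seomlr:::selfrep_state(6, n, 0.1)
    for (sweep_i in 1:3) {  # alternate views Gauss-Seidel style
      s1 <- seomlr:::admm_solve(X, s1, abs(s2$Z), D, 0.1, xi2, 0, T1 = 30L)
      s2 <- seomlr:::admm_solve(X, s2, abs(s1$Z), D, 0.1, xi2, 0, T1 = 30L)
    }
    sum(abs(s1$Z * s2$Z))
  }
  expect_lt(overlap(50), overlap(0))
})
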