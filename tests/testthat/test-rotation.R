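test_that("positive/negative split is an exact decomposition", {
  L <- rbind(c(1, -2), c(-2, 1))
  sp <- split_pos_neg(L)
  expect_equal(sp$plus, diag(2))
  expect_equal(sp$minus, rbind(c(0, 2), c(2, 0)))

  Lp <- matrix(abs(rnorm(9)), 3, 3)
  expect_equal(split_pos_neg(Lp)$minus, matrix(0, 3, 3))

  set.seed(1)
  Lr <- matrix(rnorm(25), 5, 5)
  sp <- split_pos_neg(Lr)
  expect_equal(sp$plus - sp$minus, Lr)
  expect_equal(pmin(sp$plus, sp$minus), matrix(0, 5, 5))
})

test_that("multiplicative F update preserves nonnegativity and fixed points", {
  c <- 3; n <- 8
  Lsp <- split_pos_neg(matrix(0, n, n))

  # zero rows are absorbing (why the initialization is strictly positive)
  F0 <- matrix(0, n, c)
  expect_equal(seomlr:::update_F(F0, Lsp, indicator(rep(1:3, length.out = n)),
                                 diag(c), 1, 10), F0)

  # L = 0, GR = F with orthonormal F (F = G = R = I): exact fixed point
  lab <- rep(1:3, length.out = n)
  G <- indicator(lab)
  Fi <- diag(3)
  Fn <- Fi
  for (k in 1:50) Fn <- seomlr:::update_F(Fn, split_pos_neg(matrix(0, 3, 3)),
                                          diag(3), diag(3), 1, 1000)
  expect_lt(max(abs(Fn - Fi)), 1e-3)

  # random valid inputs stay nonnegative
  set.seed(3)
  L <- matrix(rnorm(n * n), n, n); L <- (L + t(L)) / 2
  F1 <- matrix(runif(n * c) + 0.05, n, c)
  R1 <- qr.Q(qr(matrix(rnorm(c * c), c, c)))
  out <- seomlr:::update_F(F1, split_pos_neg(L), G, R1, 0.5, 5)
  expect_true(all(out >= 0))
})

test_that("G assignment matches the exhaustive indicator oracle", {
  expect_equal(seomlr:::update_G(diag(2), diag(2)), diag(2))

  # equidistant rows break ties toward the first cluster
  Feq <- matrix(0.5, 3, 2)
  Req <- rbind(c(1, 0), c(0, 1))
  G <- seomlr:::update_G(Feq, Req)
  expect_equal(G[, 1], rep(1, 3))

  # exhaustive minimization of ||F - GR||^2 over all indicator matrices
  set.seed(4)
  for (rep_i in 1:5) {
    n <- 4; c <- 2
    F <- matrix(runif(n * c), n, c)
    R <- qr.Q(qr(matrix(rnorm(c * c), c, c)))
    G <- seomlr:::update_G(F, R)
    best <- Inf
    for (code in 0:(c^n - 1)) {
      lab <- (code %/% c^(0:(n - 1))) %% c + 1
      Gc <- indicator(lab, c)
      best <- min(best, sum((F - Gc %*% R)^2))
    }
    expect_equal(sum((F - G %*% R)^2), best, tolerance = 1e-12)
  }
  # larger instance, c = 3
  n <- 6; c <- 3
  F <- matrix(runif(n * c), n, c)
  R <- qr.Q(qr(matrix(rnorm(c * c), c, c)))
  G <- seomlr:::update_G(F, R)
  best <- Inf
  for (code in 0:(c^n - 1)) {
    lab <- (code %/% c^(0:(n - 1))) %% c + 1
    best <- min(best, sum((F - indicator(lab, c) %*% R)^2))
  }
  expect_equal(sum((F - G %*% R)^2), best, tolerance = 1e-12)
})

test_that("R update solves the orthogonal Procrustes problem", {
  expect_equal(seomlr:::update_R(diag(2), diag(2)), diag(2))

  set.seed(5)
  F <- matrix(runif(12), 6, 2)
  G <- indicator(rep(1:2, 3))
  R <- seomlr:::update_R(F, G)
  expect_lt(max(abs(crossprod(R) - diag(2))), 1e-8)

  # c = 2 grid oracle over rotations and reflections
  obj <- function(R) sum((F - G %*% R)^2)
  thetas <- seq(0, 2 * pi, by = 1e-4)
  best <- Inf
  for (th in thetas) {
    ct <- cos(th); st <- sin(th)
    best <- min(best,
                obj(rbind(c(ct, -st), c(st, ct))),     # rotation
                obj(rbind(c(ct, st), c(st, -ct))))     # reflection
  }
  expect_equal(obj(R), best, tolerance = 1e-6)

  expect_warning(Rz <- seomlr:::update_R(matrix(0, 4, 2), matrix(0, 4, 2)),
                 "all-zero")
  expect_equal(Rz, diag(2))
})

test_that("a (G, R) update pair never increases the discretization objective", {
  set.seed(6)
  for (rep_i in 1:10) {
    n <- 12; c <- 3
    F <- matrix(runif(n * c), n, c)
    G <- indicator(sample(1:c, n, replace = TRUE), c)
    R <- qr.Q(qr(matrix(rnorm(c * c), c, c)))
    before <- sum((F - G %*% R)^2)
    G2 <- seomlr:::update_G(F, R)
    mid <- sum((F - G2 %*% R)^2)
    R2 <- seomlr:::update_R(F, G2)
    after <- sum((F - G2 %*% R2)^2)
    expect_lte(mid, before + 1e-12)
    expect_lte(after, mid + 1e-12)
  }
})

test_that("rotation solver recovers planted structure and respects stopping", {
  # two disconnected cliques of 5
  lab <- rep(1:2, each = 5)
  S <- outer(lab, lab, "==") * 1; diag(S) <- 0
  L <- graph_laplacian(S)

  set.seed(7)
  for (eta in c(0.1, 1, 10)) {
    # block-constant F0 with a small positive perturbation
    F0 <- indicator(lab) * 0.4 + matrix(runif(10 * 2, 0, 0.05), 10, 2)
    rot <- rotation_solve(L, F0, diag(2), matrix(0, 10, 2),
                          eta = eta, sigma = 10)
    expect_equal(nmi(rot$labels, lab), 1,
                 info = paste("eta =", eta))
    expect_true(all(rot$F >= 0))
    expect_lt(max(abs(crossprod(rot$R) - diag(2))), 1e-8)
  }

  # a huge tolerance exits after one iteration
  F0 <- matrix(runif(20), 10, 2)
  rot1 <- rotation_solve(L, F0, diag(2), NULL, eta = 1, sigma = 10, eps = 100)
  expect_equal(rot1$n_iter, 1L)
  expect_true(rot1$converged)

  # determinism: identical inputs give identical output
  rotA <- rotation_solve(L, F0, diag(2), NULL, eta = 1, sigma = 10)
  rotB <- rotation_solve(L, F0, diag(2), NULL, eta = 1, sigma = 10)
  expect_identical(rotA, rotB)

  # F stays nonnegative along the whole trajectory
  Lsp <- split_pos_neg(L)
  F <- F0; R <- diag(2); G <- matrix(0, 10, 2)
  for (k in 1:30) {
    F <- seomlr:::update_F(F, Lsp, G, R, 1, 10)
    expect_true(all(F >= 0))
    G <- seomlr:::update_G(F, R)
    expect_equal(rowSums(G), rep(1, 10))
    R <- seomlr:::update_R(F, G)
    expect_lt(max(abs(crossprod(R) - diag(2))), 1e-8)
  }
})
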