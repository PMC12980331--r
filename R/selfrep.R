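# Per-view ADMM solver for the sparse self-representation subproblem
#
#   min ||E||_1 + xi1 ||Z||_1 + xi2 sum_{w != v} ||Z (.) Z^(w)||_1
#       + xi3 sum_ij D_ij |Z_ij|
#   s.t. X = X Z + E, diag(Z) = 0
#
# solved through the splitting C = Z - diag(Z) with duals Q1 (for
# X - XC - E) and Q2 (for C - Z + diag(Z)) and an increasing penalty mu.
# D couples the representation to the current consensus embedding F:
# entries of Z between samples far apart in F are shrunk harder.

#' Soft-thresholding (shrinkage) operator
#'
#' Elementwise `sign(a) * max(|a| - tau, 0)` — the proximal operator of the
#' l1 norm.
#'
#' @param A numeric matrix (or vector).
#' @param tau nonnegative threshold: scalar or array of the same shape as `A`.
#' @return shrunk array of the same shape.
#' @export
soft_threshold <- function(A, tau) {
  if (any(tau < 0)) stop("soft_threshold: negative threshold", call. = FALSE)
  if (length(tau) != 1L && !identical(dim(A), dim(tau)) && length(tau) != length(A))
    stop("soft_threshold: threshold shape mismatch", call. = FALSE)
  sign(A) * pmax(abs(A) - tau, 0)
}

#' Pairwise embedding distances
#'
#' `D[i, j] = 0.5 * ||f_i - f_j||^2` for row vectors `f_i` of the embedding
#' `F`; symmetric with zero diagonal.
#'
#' @param F n x c numeric matrix.
#' @return n x n nonnegative matrix.
#' @export
embedding_distance <- function(F) {
  check_finite(F, "embedding F")
  D <- 0.5 * as.matrix(stats::dist(F))^2
  dimnames(D) <- NULL
  D
}

# Fresh zero-initialized ADMM state for one view (d x n data matrix).
selfrep_state <- function(d, n, mu0) {
  list(Z = matrix(0, n, n), E = matrix(0, d, n), C = matrix(0, n, n),
       Q1 = matrix(0, d, n), Q2 = matrix(0, n, n), mu = mu0)
}

# Z-hat = S_{thresh}(C + Q2/mu), thresh = (xi1*1 + xi2*sum_w |Z^(w)| + xi3*D)/mu,
# then zero the diagonal. `sum_abs_other` is sum_{w != v} |Z^(w)| precomputed.
update_Z <- function(state, sum_abs_other, D, xi1, xi2, xi3) {
  thresh <- (xi1 + xi2 * sum_abs_other + xi3 * D) / state$mu
  Zhat <- soft_threshold(state$C + state$Q2 / state$mu, thresh)
  diag(Zhat) <- 0
  Zhat
}

update_E <- function(state, X, XC) {
  soft_threshold(X - XC + state$Q1 / state$mu, 1 / state$mu)
}

# Solve (X'X + I) C = X'(X - E + Q1/mu) + Z - Q2/mu given the cached Cholesky
# factor of (X'X + I). Z carries a zero diagonal already.
update_C <- function(state, X, chol_fac) {
  rhs <- crossprod(X, X - state$E + state$Q1 / state$mu) + state$Z - state$Q2 / state$mu
  if (!all(is.finite(rhs))) stop("update_C: non-finite right-hand side", call. = FALSE)
  backsolve(chol_fac, backsolve(chol_fac, rhs, transpose = TRUE))
}

update_duals <- function(state, X, XC, rho, mu_max) {
  state$Q1 <- state$Q1 + state$mu * (X - XC - state$E)
  state$Q2 <- state$Q2 + state$mu * (state$C - state$Z)
  state$mu <- min(rho * state$mu, mu_max)
  state
}

# Run the inner ADMM loop for one view. Iteration order follows the published
# scheme: Z, E, C, duals, mu; exit when ||X - XC - E||_inf < eps or after T1
# sweeps. Returns the updated state plus iteration count and final residual.
admm_solve <- function(X, state, sum_abs_other, D, xi1, xi2, xi3,
                       chol_fac = NULL, T1 = 30L, eps = 2e-4,
                       rho = 1.2, mu_max = 1e8) {
  if (is.null(chol_fac)) chol_fac <- chol(crossprod(X) + diag(ncol(X)))
  XC <- X %*% state$C
  res <- Inf
  it <- 0L
  for (it in seq_len(T1)) {
    state$Z <- update_Z(state, sum_abs_other, D, xi1, xi2, xi3)
    state$E <- update_E(state, X, XC)
    state$C <- update_C(state, X, chol_fac)
    XC <- X %*% state$C
    state <- update_duals(state, X, XC, rho, mu_max)
    if (!all(is.finite(state$C)) || !all(is.finite(state$Z)))
      stop("admm_solve: non-finite iterate at inner iteration ", it, call. = FALSE)
    res <- max(abs(X - XC - state$E))
    if (res < eps) break
  }
  state$n_iter <- it
  state$residual <- res
  state
}
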