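# Alternating solver for the embedding subproblem
#
#   min_{F, G, R}  Tr(F' L F) + eta ||F - G R||_F^2
#   s.t. F >= 0 (near-orthonormal via the sigma penalty), R'R = I, G indicator
#
# F is refined by a nonnegative multiplicative update, G by nearest-row
# assignment, and R by the orthogonal Procrustes solution — extracting a hard
# clustering from the continuous embedding inside the optimization instead of
# a separate k-means step.

#' Positive/negative part split of a matrix
#'
#' `L+ = (|L| + L)/2`, `L- = (|L| - L)/2`; both nonnegative with
#' `L = L+ - L-`.
#'
#' @param L numeric matrix.
#' @return list with elements `plus` and `minus`.
#' @export
split_pos_neg <- function(L) {
  list(plus = pmax(L, 0), minus = pmax(-L, 0))
}

# Multiplicative update of the nonnegative embedding F. Lsplit is
# split_pos_neg(L) precomputed; denominators floored to keep the ratio finite.
update_F <- function(F, Lsplit, G, R, eta, sigma, floor = 1e-12) {
  GR <- eta * (G %*% R)
  num <- Lsplit$minus %*% F + pmax(GR, 0) + sigma * F
  den <- Lsplit$plus %*% F + pmax(-GR, 0) + eta * F + sigma * (F %*% crossprod(F))
  Fnew <- F * num / pmax(den, floor)
  if (!all(is.finite(Fnew))) stop("update_F: non-finite result", call. = FALSE)
  Fnew
}

# Hard assignment: row i of G selects the row r_k of R nearest to f_i in
# squared Euclidean distance; ties break to the smallest k.
update_G <- function(F, R) {
  d2 <- outer(rowSums(F^2), rowSums(R^2), `+`) - 2 * tcrossprod(F, R)
  k <- max.col(-d2, ties.method = "first")
  G <- matrix(0, nrow(F), nrow(R))
  G[cbind(seq_len(nrow(F)), k)] <- 1
  G
}

# Orthogonal Procrustes: with G'F = U S V', R = U V' minimizes ||F - G R||_F^2
# over R'R = I. A degenerate all-zero G'F falls back to the identity.
update_R <- function(F, G) {
  M <- crossprod(G, F)
  if (all(M == 0)) {
    warning("update_R: G'F is all-zero; returning identity rotation")
    return(diag(ncol(F)))
  }
  sv <- svd(M)
  sv$u %*% t(sv$v)
}

#' Spectral-rotation solver for the embedding subproblem
#'
#' Alternates the F / G / R updates until the rotation stabilizes
#' (`||R_(t+1) - R_t||_2 < eps`, spectral norm) or `T2` iterations.
#'
#' @param L combined n x n Laplacian.
#' @param F0 initial embedding, n x c, strictly positive.
#' @param R0 initial c x c orthonormal rotation.
#' @param G0 initial indicator (zeros allowed; the first G is produced inside
#'   the loop).
#' @param eta discretization weight.
#' @param sigma orthonormality penalty on `F'F = I`.
#' @param T2 maximum iterations (default 3000).
#' @param eps rotation-change tolerance (default 2e-4).
#' @return list with `F`, `G`, `R`, `labels` (argmax of G rows), `n_iter`,
#'   `converged`.
#' @export
rotation_solve <- function(L, F0, R0, G0 = NULL, eta = 1, sigma = 10,
                           T2 = 3000L, eps = 2e-4) {
  n <- nrow(L); c <- ncol(F0)
  stopifnot(nrow(F0) == n, nrow(R0) == c, ncol(R0) == c)
  Lsplit <- split_pos_neg(L)
  F <- F0; R <- R0
  G <- G0 %||% matrix(0, n, c)
  it <- 0L; converged <- FALSE
  for (it in seq_len(T2)) {
    Fnew <- update_F(F, Lsplit, G, R, eta, sigma)
    dF <- max(abs(Fnew - F))
    F <- Fnew
    G <- update_G(F, R)
    Rnew <- update_R(F, G)
    dR <- norm(Rnew - R, type = "2")
    R <- Rnew
    # R alone can stall while F is still drifting under a weak graph term,
    # so convergence requires both the rotation and the embedding to settle.
    if (dR < eps && dF < eps) { converged <- TRUE; break }
  }
  list(F = F, G = G, R = R, labels = max.col(G, ties.method = "first"),
       n_iter = it, converged = converged)
}

# Random positive init for F (columns scaled to unit norm) and a random
# orthonormal R, as used at the start of the outer loop.
init_embedding <- function(n, c) {
  F <- matrix(stats::runif(n * c), n, c)
  F <- sweep(F, 2L, sqrt(colSums(F^2)), `/`)
  R <- qr.Q(qr(matrix(stats::rnorm(c * c), c, c)))
  list(F = F, R = R)
}
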