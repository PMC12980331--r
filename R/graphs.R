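# Graph Laplacians from self-representations and from base clusterings, the
# self-weighted ensemble coefficients beta_p, and the combined Laplacian that
# drives the consensus embedding.

#' Symmetric affinity from a self-representation matrix
#'
#' `S = (|Z| + |Z'|) / 2` — symmetric and nonnegative, so its Laplacian is
#' positive semidefinite. Setting `abs = FALSE` gives the signed
#' symmetrization `(Z + Z') / 2` for cross-checking; it is not the default
#' because a signed affinity can yield an indefinite Laplacian.
#'
#' @param Z n x n self-representation matrix.
#' @param abs use elementwise absolute values (default).
#' @return n x n symmetric affinity.
#' @export
affinity_from_Z <- function(Z, abs = TRUE) {
  check_finite(Z, "Z")
  if (abs) (base::abs(Z) + base::abs(t(Z))) / 2 else (Z + t(Z)) / 2
}

#' Unnormalized graph Laplacian
#'
#' `L = D - S` with `D` the diagonal of row sums of the affinity `S`. Rows of
#' `L` sum to zero; for nonnegative `S`, `L` is positive semidefinite and
#' `Tr(F' L F) = 0.5 * sum_ij S_ij ||f_i - f_j||^2` measures how smooth an
#' embedding `F` is over the graph.
#'
#' @param S n x n symmetric affinity.
#' @return n x n Laplacian matrix.
#' @export
graph_laplacian <- function(S) {
  if (!is_square(S)) stop("S must be square", call. = FALSE)
  L <- -S
  diag(L) <- diag(L) + rowSums(S)
  L
}

#' Co-membership Laplacian of a base clustering
#'
#' The affinity is the block-1 co-membership matrix `S_p = Y_p Y_p'`
#' (`S_p[i, j] = 1` iff samples i and j share a cluster, diagonal included;
#' self-loops cancel in the Laplacian).
#'
#' @param base a [base_clustering()] (or a bare indicator matrix `Y`).
#' @return list with the affinity `S` and Laplacian `L`.
#' @export
base_graph <- function(base) {
  Y <- if (inherits(base, "base_clustering")) base$Y else base
  S <- tcrossprod(Y)
  list(S = S, L = graph_laplacian(S))
}

# Tr(F' L F) without forming F' L F.
tr_FLF <- function(F, L) sum(F * (L %*% F))

#' Self-weighted ensemble coefficients
#'
#' `beta_p = 1 / (2 Tr(F' L_p F))`: base clusterings whose partition agrees
#' better with the current embedding `F` (smaller trace) receive larger
#' weight, with no tuning parameter. The trace is floored at `eps_tr` so a
#' base partition that matches `F` exactly yields a finite weight.
#'
#' @param F n x c embedding.
#' @param base_laplacians list of n x n base Laplacians `L_p`.
#' @param eps_tr trace floor (default 1e-8).
#' @return positive numeric vector of length P.
#' @export
compute_beta <- function(F, base_laplacians, eps_tr = 1e-8) {
  check_finite(F, "embedding F")
  tr <- vapply(base_laplacians, function(L) tr_FLF(F, L), numeric(1L))
  1 / (2 * pmax(tr, eps_tr))
}

#' Combined Laplacian for the embedding subproblem
#'
#' `L = xi3 * (sum_v L^(v) + delta * sum_p beta_p L_p)`; `delta = 0` drops the
#' base-clustering ensemble entirely (the representation-only variant).
#'
#' @param view_laplacians list of per-view Laplacians.
#' @param base_laplacians list of base-clustering Laplacians (may be empty).
#' @param beta ensemble weights, length matching `base_laplacians`.
#' @param xi3 consistency weight (scheduled in the outer loop).
#' @param delta base-ensemble balance weight.
#' @return n x n symmetric matrix.
#' @export
combine_laplacian <- function(view_laplacians, base_laplacians = list(),
                              beta = numeric(0), xi3 = 1, delta = 1) {
  L <- Reduce(`+`, view_laplacians)
  if (delta != 0 && length(base_laplacians) > 0L) {
    stopifnot(length(beta) == length(base_laplacians))
    for (p in seq_along(base_laplacians)) L <- L + delta * beta[p] * base_laplacians[[p]]
  }
  xi3 * L
}
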