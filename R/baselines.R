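# Built-in base-clustering providers: normalized-cuts spectral clustering on
# a locally scaled Gaussian k-NN graph, seeded k-means, and a compact
# similarity network fusion (SNF) following the 2014 cross-diffusion
# formulation. Each provider is a pure function of (data, params, seed) and
# returns a base_clustering usable as an ensemble input to seomlr().

#' Spectral clustering of one view
#'
#' Normalized-cuts spectral clustering on a Gaussian-kernel k-NN affinity with
#' local-scaling bandwidths (`sigma_i` = distance to the K-th neighbour):
#' take the bottom `c` eigenvectors of the symmetric normalized Laplacian,
#' row-normalize, and k-means the embedded samples.
#'
#' @param X feature matrix (features x samples) or an [omics_view()].
#' @param c number of clusters.
#' @param seed RNG seed for the k-means step.
#' @param K neighbourhood size (default 15, capped at n - 1).
#' @param name provider label.
#' @return a [base_clustering()].
#' @export
spectral_cluster <- function(X, c, seed = NULL, K = 15L, name = "spectral") {
  X <- unclass(X)
  n <- ncol(X)
  c <- as.integer(c)
  if (c >= n) {  # degenerate: every sample its own cluster (or more asked than exist)
    return(base_clustering(stats::setNames(seq_len(n), colnames(X)), name = name))
  }
  W <- local_scaling_affinity(t(X), K = min(K, n - 1L))
  spectral_from_affinity(W, c, seed = seed, name = name,
                         sample_ids = colnames(X))
}

# Locally scaled Gaussian affinity on a symmetrized k-NN graph; rows of `P`
# are samples. W_ij = exp(-d_ij^2 / (sigma_i sigma_j)) kept where j is among
# i's K nearest neighbours (or vice versa).
local_scaling_affinity <- function(P, K) {
  d <- as.matrix(stats::dist(P))
  n <- nrow(d)
  K <- max(1L, min(K, n - 1L))
  sorted <- apply(d, 1L, sort)              # columns: sorted distances per sample
  sigma <- sorted[K + 1L, ]                 # K-th neighbour (row 1 is self, 0)
  pos <- sorted[sorted > 0]
  sigma[sigma <= 0] <- if (length(pos) > 0L) min(pos) else 1
  W <- exp(-d^2 / outer(sigma, sigma))
  # k-NN mask (union of directed neighbourhoods)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(K + 1L)]
    keep[i, nb] <- TRUE
  }
  keep <- keep | t(keep)
  W[!keep] <- 0
  diag(W) <- 0
  W
}

# Normalized-cuts partitioning of a given affinity matrix.
spectral_from_affinity <- function(W, c, seed = NULL, name = "spectral",
                                   sample_ids = NULL) {
  n <- nrow(W)
  deg <- rowSums(W)
  deg[deg <= 0] <- .Machine$double.eps
  Dm <- 1 / sqrt(deg)
  Lsym <- diag(n) - (Dm * W) * rep(Dm, each = n)  # I - D^{-1/2} W D^{-1/2}
  eig <- eigen(Lsym, symmetric = TRUE)
  U <- eig$vectors[, n - seq_len(c) + 1L, drop = FALSE]  # c smallest eigenvalues
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  km <- with_seed(seed, stats::kmeans(U, centers = c, nstart = 10L, iter.max = 100L))
  base_clustering(stats::setNames(km$cluster, sample_ids), name = name)
}

#' k-means clustering of one view or a concatenated dataset
#'
#' Lloyd's algorithm on samples-as-rows with 10 seeded restarts; given a
#' [multi_omics_dataset()], the z-scored views are stacked feature-wise first.
#'
#' @param X feature matrix (features x samples), [omics_view()], or
#'   [multi_omics_dataset()].
#' @param c number of clusters.
#' @param seed RNG seed.
#' @param name provider label.
#' @return a [base_clustering()].
#' @export
kmeans_cluster <- function(X, c, seed = NULL, name = "kmeans") {
  if (inherits(X, "multi_omics")) {
    mats <- lapply(X$views, function(v) {
      v <- unclass(v)
      sds <- apply(v, 1L, stats::sd); sds[sds == 0] <- 1
      (v - rowMeans(v)) / sds
    })
    X <- do.call(rbind, mats)
  } else X <- unclass(X)
  km <- with_seed(seed, stats::kmeans(t(X), centers = c, nstart = 10L,
                                      iter.max = 100L))
  base_clustering(stats::setNames(km$cluster, colnames(X)), name = name)
}

#' Similarity network fusion of multiple views
#'
#' Builds per-view scaled-exponential-kernel affinities, sparsifies them to
#' K-NN local kernels, runs `t_snf` cross-diffusion iterations in which each
#' view's network is propagated through the average of the others, and
#' spectral-clusters the fused network. Requires at least two views.
#'
#' @param views a [multi_omics_dataset()] or list of feature matrices.
#' @param c number of clusters for the final spectral step.
#' @param K neighbourhood size (default 20).
#' @param t_snf diffusion iterations (default 20).
#' @param mu kernel bandwidth scale (default 0.5).
#' @param seed RNG seed for the final k-means.
#' @param name provider label.
#' @return a [base_clustering()]; the fused affinity is attached as
#'   `attr(, "W")`.
#' @export
snf_fuse <- function(views, c, K = 20L, t_snf = 20L, mu = 0.5, seed = NULL,
                     name = "SNF") {
  ds <- as_multi_omics(views)
  V <- length(ds$views)
  if (V < 2L)
    stop("SNF requires at least two views; it does not work with a single data type",
         call. = FALSE)
  n <- length(ds$sample_ids)
  K <- max(1L, min(K, n - 1L))
  Ws <- lapply(ds$views, function(v) snf_affinity(t(unclass(v)), K = K, mu = mu))
  Wf <- snf_diffuse(Ws, K = K, t_snf = t_snf)
  out <- spectral_from_affinity(Wf, c, seed = seed, name = name,
                                sample_ids = ds$sample_ids)
  attr(out, "W") <- Wf
  out
}

# Scaled exponential similarity kernel (samples in rows of P):
# eps_ij = (mean_K(i) + mean_K(j) + d_ij) / 3, W_ij = N(d_ij; 0, mu * eps_ij).
snf_affinity <- function(P, K, mu = 0.5) {
  d <- as.matrix(stats::dist(P))
  n <- nrow(d)
  sorted <- apply(d, 1L, sort)
  meanK <- colMeans(sorted[2:(K + 1L), , drop = FALSE])
  eps <- (outer(meanK, meanK, `+`) + d) / 3
  eps[eps <= 0] <- .Machine$double.eps
  stats::dnorm(d, mean = 0, sd = mu * eps)
}

# Full-kernel row normalization with the 1/2 diagonal convention: off-diagonal
# mass sums to 1/2 per row, diagonal fixed at 1/2 (keeps the diffusion
# numerically stable).
snf_normalize <- function(W) {
  rs <- rowSums(W) - diag(W)
  rs[rs == 0] <- 1
  P <- W / (2 * rs)
  diag(P) <- 0.5
  P
}

# Local kernel: keep each row's K largest similarities, renormalized to a
# row-stochastic sparse operator.
snf_local_kernel <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(W[i, ], decreasing = TRUE)[seq_len(K)]
    S[i, nb] <- W[i, nb]
  }
  rs <- rowSums(S)
  rs[rs == 0] <- 1
  S / rs
}

# Cross-diffusion of the per-view networks.
snf_diffuse <- function(Ws, K, t_snf) {
  V <- length(Ws)
  Ps <- lapply(Ws, function(W) {
    P <- snf_normalize(W)
    (P + t(P)) / 2
  })
  Ss <- lapply(Ws, snf_local_kernel, K = K)
  for (iter in seq_len(t_snf)) {
    nextP <- vector("list", V)
    for (v in seq_len(V)) {
      others <- Reduce(`+`, Ps[-v]) / (V - 1L)
      P <- Ss[[v]] %*% others %*% t(Ss[[v]])
      P <- snf_normalize(P)
      nextP[[v]] <- (P + t(P)) / 2
    }
    Ps <- nextP
  }
  W <- Reduce(`+`, Ps) / V
  W <- snf_normalize(W)
  (W + t(W) + diag(nrow(W))) / 2
}
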