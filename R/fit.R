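# Outer alternating loop: ensemble weights beta_p -> per-view ADMM for
# (Z^(v), E^(v)) under the scheduled (xi1, xi2, xi3) -> combined Laplacian ->
# spectral-rotation solve for (F, G, R); repeated until the co-clustering
# matrix G G' stops changing or T outer iterations.

#' Control parameters for [seomlr()]
#'
#' @param alpha exclusivity weight (`xi2 = alpha`, constant over outer
#'   iterations).
#' @param beta scale of the consistency weight (`xi3 = beta * nu^(t-1)`,
#'   growing as the embedding becomes trustworthy).
#' @param delta balance between view Laplacians and the base-clustering
#'   ensemble; `delta = 0` switches the ensemble off.
#' @param eta weight of the discretization term `||F - G R||_F^2`.
#' @param sigma penalty enforcing `F'F = I` in the multiplicative update.
#' @param nu schedule base: `xi1 = nu^(1-t)` (sparsity, decaying) and
#'   `xi3 = beta * nu^(t-1)`.
#' @param rho ADMM penalty growth factor (`mu <- rho * mu` each inner sweep).
#' @param eps convergence tolerance of the inner loops (ADMM constraint
#'   residual in the max norm; rotation change in the spectral norm).
#' @param T,T1,T2 maximum outer / ADMM / rotation iterations.
#' @param mu0,mu_max initial and maximal ADMM penalty.
#' @param gtol threshold on `max|GG'_(t+1) - GG'_t|`; on binary co-clustering
#'   matrices any value below 1 means "identical partition".
#' @param eps_tr floor for `Tr(F' L_p F)` in the ensemble weights.
#' @return a list of class `"seomlr_control"`.
#' @export
seomlr_control <- function(alpha = 0.1, beta = 1, delta = 10, eta = 0.1,
                           sigma = 10, nu = 1.2, rho = 1.2, eps = 2e-4,
                           T = 10L, T1 = 30L, T2 = 3000L,
                           mu0 = 0.1, mu_max = 1e8, gtol = 0.05,
                           eps_tr = 1e-8) {
  stopifnot(nu > 1, rho > 1, eta > 0, eps > 0, mu0 > 0, mu_max >= mu0,
            alpha >= 0, beta >= 0, delta >= 0, sigma >= 0,
            T >= 1, T1 >= 1, T2 >= 1)
  structure(list(alpha = alpha, beta = beta, delta = delta, eta = eta,
                 sigma = sigma, nu = nu, rho = rho, eps = eps,
                 T = as.integer(T), T1 = as.integer(T1), T2 = as.integer(T2),
                 mu0 = mu0, mu_max = mu_max, gtol = gtol, eps_tr = eps_tr),
            class = "seomlr_control")
}

# Regularization schedule at outer iteration t (1-based): sparsity decays,
# embedding consistency grows, exclusivity stays constant.
schedule_at <- function(t, control) {
  list(xi1 = control$nu^(1 - t),
       xi2 = control$alpha,
       xi3 = control$beta * control$nu^(t - 1))
}

#' One-step multi-omics subspace clustering
#'
#' Jointly learns per-view sparse self-representations `Z^(v)` (with relaxed
#' exclusivity across views), a consensus nonnegative spectral embedding `F`
#' self-weighted by base-clustering Laplacians, and a discrete cluster
#' indicator `G` via spectral rotation — one optimization, no post-hoc
#' k-means.
#'
#' @param views a [multi_omics_dataset()], or a list of feature matrices
#'   (features x samples over the same samples) / [omics_view()] objects.
#' @param c target number of clusters (>= 2).
#' @param bases optional list of base clusterings ([base_clustering()]
#'   objects or plain label vectors) whose co-membership graphs guide the
#'   embedding; when empty, `delta` is forced to 0.
#' @param control a [seomlr_control()] list.
#' @param two_step if `TRUE`, discard the rotation's discrete indicator and
#'   derive labels by k-means on the rows of the final continuous `F`
#'   (10 restarts) — the classic two-step baseline, for comparison.
#' @param pca_components optional number of principal components per view
#'   (applied via [pca_preprocess()] before fitting).
#' @param scale if `TRUE` (default), each view is preprocessed by z-scoring
#'   features and normalizing every sample column to unit Euclidean norm —
#'   the standard conditioning for sparse self-representation, without which
#'   shared mean/scale directions dominate `Z`. Set `FALSE` if the input is
#'   already normalized.
#' @param seed integer seed governing the random initialization of `F` and
#'   `R` (and the two-step k-means); the fit is deterministic given the seed.
#' @param log_file optional path; per-iteration objective terms and the
#'   ensemble-weight trace are appended as plain text.
#' @return an object of class `"seomlr"`: a list with `labels` (1-based,
#'   named by sample ID), `G`, `F`, `R`, `beta`, `Z` and `E` (per view),
#'   `objective` (per-outer-iteration diagnostics data frame), `n_iter`,
#'   `converged`, `c`, `sample_ids`, `control`, `call`.
#' @examples
#' sim <- simulate_multiomics(n = 60, c_true = 3, d = 40, effect = 3, seed = 1)
#' fit <- seomlr(sim$dataset, c = 3, seed = 1)
#' table(fit$labels, sim$truth)
#' @export
seomlr <- function(views, c, bases = list(), control = seomlr_control(),
                   two_step = FALSE, pca_components = NULL, scale = TRUE,
                   seed = NULL, log_file = NULL) {
  cl <- match.call()
  ds <- as_multi_omics(views)
  if (!is.null(pca_components))
    ds <- multi_omics_dataset(lapply(ds$views, pca_preprocess, k = pca_components))
  n <- length(ds$sample_ids)
  V <- length(ds$views)
  c <- as.integer(c)
  if (c < 2L) stop("c must be >= 2", call. = FALSE)
  if (c > n) stop("c = ", c, " exceeds the number of samples (", n, ")", call. = FALSE)

  bases <- normalize_bases(bases, ds)
  P <- length(bases)
  delta <- if (P == 0L) 0 else control$delta
  base_L <- lapply(bases, function(b) base_graph(b)$L)

  Xs <- lapply(ds$views, function(v) {
    X <- unclass(v)
    if (scale) X <- unit_columns(zscore_features(X))
    X
  })
  chol_facs <- lapply(Xs, function(X) chol(crossprod(X) + diag(n)))
  states <- lapply(Xs, function(X) selfrep_state(nrow(X), n, control$mu0))

  init <- with_seed(seed, init_embedding(n, c))
  F <- init$F; R <- init$R
  G <- matrix(0, n, c)
  co_prev <- NULL
  beta <- rep(NA_real_, P)
  trace <- vector("list", control$T)
  log_con <- if (!is.null(log_file)) file(log_file, open = "at") else NULL
  if (!is.null(log_con)) {
    on.exit(close(log_con), add = TRUE)
    writeLines(c("# seomlr run", paste0("# seed: ", seed %||% "NULL"),
                 paste0("# n=", n, " V=", V, " c=", c, " P=", P),
                 paste0("# control: ", paste(names(control), unlist(control),
                                             sep = "=", collapse = " "))),
               log_con)
  }

  n_iter <- 0L; converged <- FALSE
  for (t in seq_len(control$T)) {
    n_iter <- t
    sch <- schedule_at(t, control)

    if (P > 0L) beta <- compute_beta(F, base_L, control$eps_tr)

    # Per-view ADMM (Gauss-Seidel: each view sees the others' latest Z).
    # Z, E, C are warm-started across outer iterations; duals and mu restart
    # so the scheduled thresholds stay active.
    D <- embedding_distance(F)
    for (v in seq_len(V)) {
      sum_other <- Reduce(`+`, lapply(states[-v], function(s) abs(s$Z)),
                          accumulate = FALSE) %||% matrix(0, n, n)
      if (V == 1L) sum_other <- matrix(0, n, n)
      st <- states[[v]]
      st$Q1[] <- 0; st$Q2[] <- 0; st$mu <- control$mu0
      states[[v]] <- admm_solve(Xs[[v]], st, sum_other, D,
                                sch$xi1, sch$xi2, sch$xi3,
                                chol_fac = chol_facs[[v]],
                                T1 = control$T1, eps = control$eps,
                                rho = control$rho, mu_max = control$mu_max)
    }

    view_L <- lapply(states, function(s) graph_laplacian(affinity_from_Z(s$Z)))
    L <- combine_laplacian(view_L, base_L, beta, sch$xi3, delta)
    # Condition the rotation subproblem: the combined Laplacian's scale grows
    # with the xi3 schedule and the self-weights, while eta and sigma are
    # fixed; rescaling L to max degree sigma keeps the graph and
    # orthogonality terms in the regime where the multiplicative update is
    # stable. Relative weights within L are untouched.
    dmax <- max(diag(L))
    if (dmax > 0) L <- (control$sigma / dmax) * L

    # Re-anchor the discrete readout to the current embedding: the rotation
    # restarts axis-aligned (R = I), so each cluster column of the
    # nonnegative F maps to its own rotation row. A carried-over rotation
    # whose empty rows point away from the nonnegative orthant can absorb
    # all samples into one cluster.
    R <- diag(c)
    G <- if (t == 1L) matrix(0, n, c) else update_G(F, R)

    rot <- rotation_solve(L, F, R, G, eta = control$eta, sigma = control$sigma,
                          T2 = control$T2, eps = control$eps)
    F <- rot$F; G <- rot$G; R <- rot$R
    if (!all(is.finite(F))) stop("non-finite embedding at outer iteration ", t, call. = FALSE)

    obj <- objective_terms(states, F, G, R, L, sch, control)
    trace[[t]] <- data.frame(iter = t, xi1 = sch$xi1, xi3 = sch$xi3,
                             obj, rot_iter = rot$n_iter)
    if (!is.null(log_con))
      writeLines(sprintf("iter %d: objective=%.6g selfrep=%.6g trace=%.6g rotation=%.6g beta=[%s]",
                         t, obj$objective, obj$selfrep, obj$laplacian, obj$rotation,
                         paste(signif(beta, 4), collapse = ", ")), log_con)

    co <- tcrossprod(G)
    if (!is.null(co_prev) && max(abs(co - co_prev)) < control$gtol) {
      converged <- TRUE
      break
    }
    co_prev <- co
  }

  labels <- max.col(G, ties.method = "first")
  method <- "one-step"
  if (two_step) {
    km_seed <- if (is.null(seed)) NULL else seed + 1L
    km <- with_seed(km_seed, stats::kmeans(F, centers = c, nstart = 10L,
                                           iter.max = 100L))
    labels <- km$cluster
    method <- "two-step"
  }
  names(labels) <- ds$sample_ids

  structure(list(labels = labels, G = G, F = F, R = R,
                 beta = if (P > 0L) stats::setNames(beta, names(bases)) else numeric(0),
                 Z = lapply(states, `[[`, "Z"), E = lapply(states, `[[`, "E"),
                 objective = do.call(rbind, trace[seq_len(n_iter)]),
                 n_iter = n_iter, converged = converged,
                 c = c, n_clusters_found = length(unique(labels)),
                 method = method, sample_ids = ds$sample_ids,
                 view_names = names(ds$views), delta = delta,
                 control = control, seed = seed, call = cl),
            class = "seomlr")
}

# Coerce the accepted input forms to a multi_omics dataset.
as_multi_omics <- function(views) {
  if (inherits(views, "multi_omics")) return(views)
  if (inherits(views, "omics_view")) views <- list(views)
  if (!is.list(views)) stop("'views' must be a list of matrices or a multi_omics dataset",
                            call. = FALSE)
  vs <- lapply(seq_along(views), function(i) {
    v <- views[[i]]
    if (inherits(v, "omics_view")) return(v)
    nm <- names(views)[i] %||% paste0("view", i)
    if (is.null(nm) || nm == "") nm <- paste0("view", i)
    if (is.null(colnames(v))) colnames(v) <- paste0("s", seq_len(ncol(v)))
    omics_view(as.matrix(v), name = nm)
  })
  multi_omics_dataset(vs)
}

normalize_bases <- function(bases, ds) {
  if (inherits(bases, "base_clustering")) bases <- list(bases)
  if (length(bases) == 0L) return(list())
  out <- lapply(seq_along(bases), function(p) {
    b <- bases[[p]]
    if (!inherits(b, "base_clustering"))
      b <- base_clustering(b, name = names(bases)[p] %||% paste0("base", p))
    if (nrow(b$Y) != length(ds$sample_ids))
      stop("base clustering '", b$name, "' has ", nrow(b$Y),
           " samples; dataset has ", length(ds$sample_ids), call. = FALSE)
    if (!is.null(b$sample_ids) && !identical(as.character(b$sample_ids), ds$sample_ids)) {
      ord <- match(ds$sample_ids, b$sample_ids)
      if (anyNA(ord)) stop("base clustering '", b$name,
                           "' is missing dataset samples", call. = FALSE)
      b <- base_clustering(stats::setNames(b$labels[ord], ds$sample_ids), name = b$name)
    }
    b
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

# All terms of the joint objective at the current iterate.
objective_terms <- function(states, F, G, R, L, sch, control) {
  selfrep <- 0
  V <- length(states)
  for (v in seq_len(V)) {
    s <- states[[v]]
    excl <- 0
    for (w in seq_len(V)) if (w != v)
      excl <- excl + sum(abs(s$Z * states[[w]]$Z))
    selfrep <- selfrep + sum(abs(s$E)) + sch$xi1 * sum(abs(s$Z)) + sch$xi2 * excl
  }
  lap <- tr_FLF(F, L)
  rot <- control$eta * sum((F - G %*% R)^2)
  data.frame(selfrep = selfrep, laplacian = lap, rotation = rot,
             objective = selfrep + lap + rot)
}

#' Two-step variant: continuous embedding plus k-means discretization
#'
#' Runs the identical joint optimization but derives the final labels by
#' k-means on the rows of the continuous embedding `F` instead of the
#' rotation's discrete indicator. Exists to quantify the information lost by
#' separating embedding from discretization.
#'
#' @inheritParams seomlr
#' @return a `"seomlr"` object with `method = "two-step"`.
#' @export
seomlr_two_step <- function(views, c, bases = list(), control = seomlr_control(),
                            seed = NULL, ...) {
  seomlr(views, c, bases = bases, control = control, two_step = TRUE,
         seed = seed, ...)
}

#' Grid search over the regularization hyperparameters
#'
#' Refits over a grid of (alpha, beta, delta, eta, sigma) values and scores
#' each cell by NMI against supplied truth labels, or (without truth) by the
#' mean pairwise NMI between the cell's fit and all other cells' fits as a
#' stability proxy.
#'
#' @inheritParams seomlr
#' @param grid named list of value vectors for any of `alpha`, `beta`,
#'   `delta`, `eta`, `sigma`; crossed.
#' @param truth optional reference labels.
#' @return data frame of grid cells with an `nmi` (or `stability`) column,
#'   best first; the winning fit in `attr(, "best_fit")`.
#' @export
seomlr_sweep <- function(views, c, bases = list(),
                         grid = list(alpha = c(0.01, 0.1), beta = c(0.1, 1)),
                         truth = NULL, control = seomlr_control(), seed = 1L) {
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  fits <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ctl <- control
    for (nm in names(cells)) ctl[[nm]] <- cells[[nm]][i]
    fits[[i]] <- seomlr(views, c, bases = bases, control = ctl, seed = seed)
  }
  if (!is.null(truth)) {
    cells$nmi <- vapply(fits, function(f) nmi(f$labels, truth), numeric(1L))
    ord <- order(-cells$nmi)
  } else {
    labs <- lapply(fits, `[[`, "labels")
    cells$stability <- vapply(seq_along(labs), function(i) {
      others <- labs[-i]
      if (length(others) == 0L) return(1)
      mean(vapply(others, function(l) nmi(labs[[i]], l), numeric(1L)))
    }, numeric(1L))
    ord <- order(-cells$stability)
  }
  out <- cells[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "best_fit") <- fits[[ord[1L]]]
  out
}
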