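# Clustering-agreement metrics: normalized mutual information and the
# adjusted Rand index, both invariant to label permutation and renaming.

#' Normalized mutual information between two partitions
#'
#' `NMI = I(a; b) / sqrt(H(a) H(b))` with natural logarithms (the geometric-
#' mean normalization customary in multi-view clustering; `variant` selects
#' alternatives for cross-checking). Degenerate cases: 1 when both partitions
#' are single-cluster, 0 when exactly one is.
#'
#' @param a,b label vectors of equal length (any type; compared as factors).
#' @param variant normalization: `"sqrt"` (default), `"max"`, `"min"`, or
#'   `"arithmetic"` mean of the entropies.
#' @return a number in \[0, 1\].
#' @export
nmi <- function(a, b, variant = c("sqrt", "max", "min", "arithmetic")) {
  variant <- match.arg(variant)
  if (length(a) != length(b))
    stop("label vectors differ in length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  if (length(a) == 0L) stop("empty label vectors", call. = FALSE)
  tab <- table(a, b)
  n <- sum(tab)
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  Ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  Hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (Ha == 0 && Hb == 0) return(1)
  if (Ha == 0 || Hb == 0) return(0)
  pij <- tab / n
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pa, pb)[nz]))
  denom <- switch(variant,
                  sqrt = sqrt(Ha * Hb),
                  max = max(Ha, Hb),
                  min = min(Ha, Hb),
                  arithmetic = (Ha + Hb) / 2)
  max(0, min(1, mi / denom))
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance; 1 for identical partitions,
#' around 0 for independent ones (can be negative).
#'
#' @param a,b label vectors of equal length.
#' @return a number in \[-1, 1\].
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  expected <- sum_a * sum_b / tot
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Agreement report between two partitions
#'
#' @param a,b label vectors (e.g. predicted and ground-truth clusters).
#' @param extra optional named list merged into the report — a slot for
#'   quantities computed outside this package (e.g. survival endpoints such
#'   as a log-rank p-value or a concordance index for the same partition).
#' @return list of class `"agreement_report"` with `nmi`, `ari`, the
#'   `contingency` count table, and any `extra` entries.
#' @export
agreement_report <- function(a, b, extra = NULL) {
  out <- list(nmi = nmi(a, b), ari = ari(a, b), contingency = table(a, b))
  if (!is.null(extra)) {
    stopifnot(is.list(extra), !is.null(names(extra)))
    out <- c(out, extra)
  }
  structure(out, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("clustering agreement: NMI = %.4f, ARI = %.4f\n", x$nmi, x$ari))
  print(x$contingency)
  invisible(x)
}
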