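# S3 methods for fitted "seomlr" objects.

#' @export
print.seomlr <- function(x, ...) {
  cat("One-step multi-omics subspace clustering (seOMLR)\n")
  cat(sprintf("  %d samples, %d view(s)%s, c = %d (%s)\n",
              length(x$labels), length(x$Z),
              if (length(x$beta) > 0L) sprintf(", %d base clustering(s)", length(x$beta)) else "",
              x$c, x$method))
  cat(sprintf("  outer iterations: %d (%s)\n", x$n_iter,
              if (x$converged) "co-clustering converged" else "iteration cap reached"))
  cat("  cluster sizes:", paste(tabulate(x$labels, x$c), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.seomlr <- function(object, ...) {
  structure(list(fit = object,
                 sizes = tabulate(object$labels, object$c),
                 beta = object$beta,
                 objective = object$objective,
                 sparsity = vapply(object$Z, function(Z) mean(Z != 0), numeric(1L))),
            class = "summary.seomlr")
}

#' @export
print.summary.seomlr <- function(x, ...) {
  print(x$fit)
  if (length(x$beta) > 0L) {
    cat("  ensemble weights beta_p (final):\n")
    b <- x$beta / sum(x$beta)
    for (p in seq_along(x$beta))
      cat(sprintf("    %-14s %.4g (relative %.2f)\n",
                  names(x$beta)[p] %||% paste0("base", p), x$beta[p], b[p]))
  }
  cat("  Z sparsity (fraction nonzero):",
      paste(sprintf("%.3f", x$sparsity), collapse = ", "), "\n")
  cat("  final objective:", format(utils::tail(x$objective$objective, 1L)), "\n")
  invisible(x)
}

#' Cluster labels of a fit
#' @param object a fitted `"seomlr"` object.
#' @param ... unused.
#' @export
fitted.seomlr <- function(object, ...) object$labels

#' Ensemble weights of a fit
#'
#' Returns the final self-weighted ensemble coefficients `beta_p` — the
#' model's only fitted coefficients in the usual sense.
#' @param object a fitted `"seomlr"` object.
#' @param ... unused.
#' @export
coef.seomlr <- function(object, ...) object$beta

#' Self-representation residuals
#'
#' The per-view sparse error matrices `E^(v) = X^(v) - X^(v) Z^(v)` absorbed
#' by the l1 term of the model.
#' @param object a fitted `"seomlr"` object.
#' @param ... unused.
#' @export
residuals.seomlr <- function(object, ...) object$E

#' Diagnostic plot for a fit
#'
#' Left: the objective trace over outer iterations. Right (when base
#' clusterings were supplied): final ensemble weights.
#' @param x a fitted `"seomlr"` object.
#' @param ... passed to [plot()].
#' @export
plot.seomlr <- function(x, ...) {
  has_beta <- length(x$beta) > 0L
  old <- graphics::par(mfrow = c(1L, if (has_beta) 2L else 1L))
  on.exit(graphics::par(old))
  plot(x$objective$iter, x$objective$objective, type = "b", pch = 19,
       xlab = "outer iteration", ylab = "objective", main = "seOMLR objective", ...)
  if (has_beta)
    graphics::barplot(x$beta / sum(x$beta),
                      names.arg = names(x$beta) %||% seq_along(x$beta),
                      ylab = "relative ensemble weight", main = "beta_p", las = 2)
  invisible(x)
}
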