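# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream untouched".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive `k` reproducible child seeds (< 2^31) from one master seed.
child_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

is_square <- function(A) is.matrix(A) && nrow(A) == ncol(A)

check_finite <- function(A, what, context = NULL) {
  if (!all(is.finite(A))) {
    ctx <- if (is.null(context)) "" else paste0(" (", context, ")")
    stop("non-finite values in ", what, ctx, call. = FALSE)
  }
  invisible(A)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# z-score rows (features); constant features are left centered only.
zscore_features <- function(X) {
  s <- apply(X, 1L, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  (X - rowMeans(X)) / s
}

# scale columns (samples) to unit Euclidean norm.
unit_columns <- function(X) {
  cn <- sqrt(colSums(X^2))
  cn[cn == 0] <- 1
  sweep(X, 2L, cn, `/`)
}
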