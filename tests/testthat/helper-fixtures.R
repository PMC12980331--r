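# Shared fixture builders; everything is generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# small view with known dimnames
tiny_view <- function(d = 3, n = 4, name = "v", seed = 1) {
  set.seed(seed)
  omics_view(matrix(rnorm(d * n), d, n,
                    dimnames = list(paste0("f", seq_len(d)),
                                    paste0("s", seq_len(n)))),
             name = name)
}

# two Gaussian blobs, features x samples
blob_view <- function(n_per = 15, d = 10, sep = 6, name = "blobs", seed = 1) {
  set.seed(seed)
  X <- cbind(matrix(rnorm(d * n_per, 0), d, n_per),
             matrix(rnorm(d * n_per, sep), d, n_per))
  colnames(X) <- paste0("s", seq_len(2 * n_per))
  rownames(X) <- paste0("f", seq_len(d))
  list(view = omics_view(X, name = name), truth = rep(1:2, each = n_per))
}

# indicator matrix from labels
indicator <- function(labels, c = max(labels)) {
  G <- matrix(0, length(labels), c)
  G[cbind(seq_along(labels), labels)] <- 1
  G
}

# co-membership Laplacian of a label vector
partition_laplacian <- function(labels) {
  graph_laplacian(tcrossprod(indicator(labels)))
}

write_view_file <- function(view, path, sep = "\t") {
  df <- data.frame(feature_id = rownames(view), unclass(view), check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
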