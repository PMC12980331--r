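# Domain containers and delimited-table I/O for multi-omics views and
# base-clustering label sets. Views are stored features x samples, the
# orientation in which each omics platform's matrix X^(v) (d_v x n) enters the
# self-representation model X^(v) = X^(v) Z^(v) + E^(v).

#' Construct an omics view
#'
#' An omics view is one feature matrix (features in rows, samples in columns)
#' over the shared sample set, e.g. an mRNA expression, miRNA expression or
#' DNA-methylation table.
#'
#' @param values numeric matrix, `d_v` features x `n` samples, no missing
#'   values.
#' @param name view label (e.g. `"mRNA"`).
#' @param feature_ids,sample_ids identifiers; default to the dimnames of
#'   `values`.
#' @return an object of class `"omics_view"`: the validated matrix with
#'   dimnames set and the view name attached.
#' @export
omics_view <- function(values, name,
                       feature_ids = rownames(values),
                       sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (anyNA(values) || !all(is.finite(values)))
    stop("view '", name, "' contains missing or non-finite values", call. = FALSE)
  d <- nrow(values); n <- ncol(values)
  if (d < 1L) stop("view '", name, "' has no features", call. = FALSE)
  if (n < 2L) stop("view '", name, "' needs at least 2 samples", call. = FALSE)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(d))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("view '", name, "' has duplicated sample IDs", call. = FALSE)
  dimnames(values) <- list(as.character(feature_ids), sample_ids)
  structure(values, name = as.character(name), class = c("omics_view", "matrix", "array"))
}

#' @export
print.omics_view <- function(x, ...) {
  cat(sprintf("omics view '%s': %d features x %d samples\n",
              attr(x, "name"), nrow(x), ncol(x)))
  invisible(x)
}

view_name <- function(x) attr(x, "name") %||% "view"

#' Read an omics view from a delimited table
#'
#' Expects a numeric table with sample IDs in the header row and feature IDs in
#' the first column; the delimiter (tab or comma) is auto-detected. Any
#' non-numeric or missing cell is a parse error naming the offending cell.
#'
#' @param path file path.
#' @param name view label.
#' @param transpose set `TRUE` if the file is samples x features.
#' @return an [omics_view()].
#' @export
read_omics_view <- function(path, name = basename(path), transpose = FALSE) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 2L) stop("'", path, "': expected at least one data column", call. = FALSE)
  rn <- df[[1L]]
  if (anyDuplicated(rn)) stop("'", path, "': duplicated row IDs", call. = FALSE)
  cn <- colnames(df)[-1L]   # before subsetting, which mangles duplicates
  if (anyDuplicated(cn))
    stop("'", path, "': duplicated sample IDs in header", call. = FALSE)
  body <- as.matrix(df[, -1L, drop = FALSE])
  colnames(body) <- cn
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body), dimnames = dimnames(body)))
  bad <- which(is.na(num) | is.nan(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("'%s': non-numeric or missing value '%s' at row '%s', column '%s'",
                 path, body[i, j], rn[i], colnames(body)[j]), call. = FALSE)
  }
  rownames(num) <- rn
  if (transpose) num <- t(num)
  omics_view(num, name = name)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Write an omics view to a delimited table
#'
#' @param view an [omics_view()] (or plain matrix with dimnames).
#' @param path output path; extension `.csv` selects comma, anything else tab.
#' @export
write_omics_view <- function(view, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(feature_id = rownames(view), unclass(view),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundle aligned views into a multi-omics dataset
#'
#' @param views list of [omics_view()] objects sharing identical sample IDs in
#'   identical order.
#' @return an object of class `"multi_omics"`: a named list of views plus the
#'   shared `sample_ids`.
#' @export
multi_omics_dataset <- function(views) {
  if (!is.list(views) || length(views) < 1L)
    stop("'views' must be a non-empty list", call. = FALSE)
  ids <- colnames(views[[1L]])
  for (v in views) {
    if (!identical(colnames(v), ids))
      stop("views must share identical sample IDs in identical order; use align_views()",
           call. = FALSE)
  }
  names(views) <- vapply(views, view_name, "")
  structure(list(views = views, sample_ids = ids), class = "multi_omics")
}

#' @export
print.multi_omics <- function(x, ...) {
  cat(sprintf("multi-omics dataset: %d view(s), %d shared samples\n",
              length(x$views), length(x$sample_ids)))
  for (v in x$views)
    cat(sprintf("  %-14s %5d features\n", view_name(v), nrow(v)))
  invisible(x)
}

#' Align views on their common samples
#'
#' Restricts every view to the intersection of sample IDs, in the first view's
#' order; dropped IDs are reported via a message. Idempotent.
#'
#' @param views list of [omics_view()] objects.
#' @return a [multi_omics_dataset()].
#' @export
align_views <- function(views) {
  if (inherits(views, "multi_omics")) views <- views$views
  ids <- Reduce(intersect, lapply(views, colnames))
  if (length(ids) == 0L) stop("views share no sample IDs", call. = FALSE)
  if (length(ids) < 2L) stop("views share fewer than 2 sample IDs", call. = FALSE)
  ids <- colnames(views[[1L]])[colnames(views[[1L]]) %in% ids]  # first view's order
  out <- lapply(views, function(v) {
    dropped <- setdiff(colnames(v), ids)
    if (length(dropped) > 0L)
      message("align_views: dropping ", length(dropped), " sample(s) from '",
              view_name(v), "': ", paste(utils::head(dropped, 5L), collapse = ", "),
              if (length(dropped) > 5L) ", ..." else "")
    omics_view(v[, ids, drop = FALSE], name = view_name(v))
  })
  multi_omics_dataset(out)
}

#' Construct a base clustering from labels
#'
#' Encodes a partition as a binary indicator matrix `Y` (n x c_p, one 1 per
#' row); distinct label values map to columns in order of first appearance.
#'
#' @param labels vector of cluster labels (integer, character or factor),
#'   optionally named by sample ID.
#' @param name provider label.
#' @param sample_ids sample IDs; default from `names(labels)`.
#' @return object of class `"base_clustering"` with elements `Y`, `labels`
#'   (integer 1..c_p), `c_p`, `name`, `sample_ids`.
#' @export
base_clustering <- function(labels, name = "base", sample_ids = names(labels)) {
  if (length(labels) < 1L) stop("empty label vector", call. = FALSE)
  lev <- unique(as.character(labels))            # first-appearance order
  lab <- match(as.character(labels), lev)
  n <- length(lab); cp <- length(lev)
  Y <- matrix(0L, n, cp)
  Y[cbind(seq_len(n), lab)] <- 1L
  if (!is.null(sample_ids)) rownames(Y) <- sample_ids
  if (any(colSums(Y) == 0L)) warning("base clustering '", name, "' has empty clusters")
  structure(list(Y = Y, labels = lab, c_p = cp, name = name,
                 sample_ids = sample_ids),
            class = "base_clustering")
}

#' @export
print.base_clustering <- function(x, ...) {
  cat(sprintf("base clustering '%s': %d samples, %d clusters (sizes: %s)\n",
              x$name, nrow(x$Y), x$c_p, paste(colSums(x$Y), collapse = ", ")))
  invisible(x)
}

#' Read / write cluster labels
#'
#' Label files are two-column delimited tables `sample_id`, `cluster` with a
#' header. `read_labels` maps distinct cluster values to indicator columns in
#' first-appearance order; `write_labels` emits 1-based integer labels.
#'
#' @param path file path.
#' @param name provider label.
#' @param dataset optional [multi_omics_dataset()]; if given, every sample in
#'   the file must be present in the dataset and rows are reordered to match.
#' @return a [base_clustering()].
#' @export
read_labels <- function(path, name = basename(path), dataset = NULL) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("'", path, "': expected columns sample_id, cluster", call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("'", path, "': duplicated sample row(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  lab <- df[[2L]]
  if (!is.null(dataset)) {
    missing <- setdiff(ids, dataset$sample_ids)
    if (length(missing) > 0L)
      stop("'", path, "': sample(s) absent from dataset: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    ord <- match(dataset$sample_ids, ids)
    if (anyNA(ord))
      stop("'", path, "': labels missing for ",
           sum(is.na(ord)), " dataset sample(s)", call. = FALSE)
    ids <- ids[ord]; lab <- lab[ord]
  }
  names(lab) <- ids
  base_clustering(lab, name = name)
}

#' @rdname read_labels
#' @param labels integer label vector, or a fitted `"seomlr"` object, or a
#'   [base_clustering()].
#' @param sample_ids sample IDs (defaults to names of the labels).
#' @export
write_labels <- function(labels, path, sample_ids = NULL) {
  if (inherits(labels, "seomlr")) {
    sample_ids <- sample_ids %||% labels$sample_ids
    labels <- labels$labels
  } else if (inherits(labels, "base_clustering")) {
    sample_ids <- sample_ids %||% labels$sample_ids
    labels <- labels$labels
  }
  sample_ids <- sample_ids %||% names(labels) %||% paste0("s", seq_along(labels))
  df <- data.frame(sample_id = sample_ids, cluster = as.integer(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' PCA preprocessing of one view
#'
#' Features are z-scored (zero-variance features dropped with a warning), then
#' projected onto the top `k` principal components; the view becomes a k x n
#' score matrix. The sign of each component is fixed by making its
#' largest-magnitude loading positive, so results are reproducible.
#'
#' @param view an [omics_view()].
#' @param k number of components, `1 <= k <= min(d_v, n)`.
#' @param seed unused (PCA here is deterministic); kept for interface symmetry
#'   with the stochastic providers.
#' @return an [omics_view()] with features `PC1..PCk`.
#' @export
pca_preprocess <- function(view, k, seed = NULL) {
  X <- unclass(view)
  sds <- apply(X, 1L, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance feature(s) from '",
            view_name(view), "' before PCA")
    X <- X[!zero, , drop = FALSE]; sds <- sds[!zero]
  }
  d <- nrow(X); n <- ncol(X)
  if (!(k >= 1L && k <= min(d, n)))
    stop("k must be in [1, min(d_v, n)] = [1, ", min(d, n), "]", call. = FALSE)
  Xz <- (X - rowMeans(X)) / sds
  pc <- stats::prcomp(t(Xz), center = FALSE, scale. = FALSE, rank. = k)
  rot <- pc$rotation; sco <- pc$x
  for (j in seq_len(k)) {               # deterministic sign convention
    i0 <- which.max(abs(rot[, j]))
    if (rot[i0, j] < 0) { rot[, j] <- -rot[, j]; sco[, j] <- -sco[, j] }
  }
  out <- t(sco[, seq_len(k), drop = FALSE])
  rownames(out) <- paste0("PC", seq_len(k))
  colnames(out) <- colnames(X)
  omics_view(out, name = view_name(view))
}
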