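#' Pearson product-moment correlation coefficient
#'
#' Thin validated wrapper used throughout the pipeline wherever the source
#' analyses report "r": fold-change concordance between assays, RNA-protein
#' correlation, and assay cross-correlations. Errors (rather than returning
#' NA) on vectors that are too short or constant, because a silent NA would
#' propagate into the correlation summaries.
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return the coefficient, in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input (zero variance)")
  stats::cor(x, y)
}

#' Pairwise Pearson-distance (or squared-Euclidean) matrix
#'
#' The clustering stages all operate on the distance `d = 1 - r` with `r`
#' the Pearson correlation, computed pairwise over genes or over samples.
#' Squared Euclidean distance is available as the alternative used in some
#' of the source heat maps, off by default.
#'
#' @param x an [expression_matrix()] or a plain numeric matrix whose *rows*
#'   are the items to compare.
#' @param axis for an `expr_matrix`: compare `"genes"` (rows) or
#'   `"samples"` (columns).
#' @param method `"pearson"` (d = 1 - r, in \[0, 2\]) or `"sqeuclidean"`.
#' @return a symmetric matrix of class `dist_matrix` with zero diagonal.
#' @export
distance_matrix <- function(x, axis = c("genes", "samples"),
                            method = c("pearson", "sqeuclidean")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  m <- if (inherits(x, "expr_matrix")) {
    if (axis == "genes") x$values else t(x$values)
  } else {
    stopifnot(is.matrix(x), is.numeric(x))
    if (axis == "samples") t(x) else x
  }
  if (ncol(m) < 3L && method == "pearson")
    stop("need at least 3 observations per vector for Pearson distance")
  if (method == "pearson") {
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0))
      stop("constant vector(s): ",
           paste(rownames(m)[sds == 0], collapse = ", "))
    d <- 1 - stats::cor(t(m))
  } else {
    d <- as.matrix(stats::dist(m))^2
  }
  # cor() can leave |r| a hair above 1 in degenerate duplicates
  d[d < 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Agglomerative clustering of a distance matrix
#'
#' Average-linkage (UPGMA) agglomerative clustering. Items are reordered
#' lexicographically by id before merging, so the resulting tree is
#' invariant to the input order of items (ties between equal-height merges
#' are then resolved identically regardless of presentation order).
#'
#' @param d a `dist_matrix` from [distance_matrix()].
#' @param method linkage passed to [stats::hclust()]; fixed default
#'   `"average"`.
#' @return an object of class `hclust` (merge history + heights), with the
#'   linkage recorded in `$method`.
#' @export
cluster_tree <- function(d, method = "average") {
  stopifnot(inherits(d, "dist_matrix") || (is.matrix(d) && isSymmetric(unclass(d))))
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  ord <- order(ids)
  dm <- unclass(d)[ord, ord, drop = FALSE]
  stats::hclust(stats::as.dist(dm), method = method)
}

#' Cut a cluster tree into k modules
#'
#' Modules are labelled with roman numerals (I, II, III, ...) in order of
#' decreasing size; ties broken by the lexicographically smallest member id.
#'
#' @param tree an `hclust` from [cluster_tree()].
#' @param k number of modules, `1 <= k <= n`.
#' @return a named character vector of class `module_assignment`
#'   (item id -> module label), with `k` recorded as an attribute.
#' @export
cut_modules <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k out of range (1..", n, ")")
  raw <- stats::cutree(tree, k = k)
  sizes <- table(raw)
  firsts <- vapply(names(sizes),
                   function(cl) min(names(raw)[raw == as.integer(cl)]),
                   character(1L))
  rank <- order(-as.integer(sizes), firsts)
  label_of <- stats::setNames(as.character(utils::as.roman(seq_len(k))),
                              names(sizes)[rank])
  out <- stats::setNames(unname(label_of[as.character(raw)]), names(raw))
  attr(out, "k") <- as.integer(k)
  class(out) <- "module_assignment"
  out
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("module_assignment: %d items in %d module(s)\n",
              length(x), attr(x, "k")))
  print(table(unclass(x)))
  invisible(x)
}

#' PCA overview of samples
#'
#' Gene-centered singular value decomposition of the expression matrix,
#' returning per-sample coordinates on the leading components; used for the
#' global "where do these cultures sit" view.
#'
#' @param x an [expression_matrix()].
#' @param n_components number of components to return (`< n samples`).
#' @return a data.frame with `sample_id`, `group`, then `PC1..PCk`;
#'   per-component variances attached as attribute `variance`
#'   (non-increasing).
#' @export
pca_overview <- function(x, n_components = 2L) {
  stopifnot(inherits(x, "expr_matrix"))
  n <- ncol(x$values)
  if (n < 2L) stop("need at least 2 samples")
  if (n_components >= n)
    stop("fewer samples than requested components")
  p <- stats::prcomp(t(x$values), center = TRUE, scale. = FALSE)
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  out <- data.frame(sample_id = colnames(x$values),
                    group = x$metadata$group, scores,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "variance") <- p$sdev[seq_len(n_components)]^2
  out
}
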