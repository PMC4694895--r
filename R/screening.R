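#' Consistency filter: genes off in every control, on in every case
#'
#' The candidate-selection rule of the screen: a gene is selected iff its
#' log2 expression is strictly below `threshold` in *every* control sample
#' and strictly above `threshold` in *every* case sample. Values exactly at
#' the threshold exclude the gene. With log2 data and the default threshold
#' of 0 this reads "consistently not expressed in controls, consistently
#' expressed in cases".
#'
#' @param expr an [expression_matrix()] with at least one sample per group.
#' @param threshold log2 cut point (default 0); must be finite.
#' @return a data.frame of class `candidate_set` with columns `gene_id`,
#'   `fc` (linear fold change, see [linear_fold_change()]), `case_mean`,
#'   `control_mean`; ordered by decreasing fold change.
#' @export
consistency_filter <- function(expr, threshold = 0) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!is.finite(threshold)) stop("threshold must be finite")
  case_ids <- group_samples(expr, "case")
  ctrl_ids <- group_samples(expr, "control")
  if (!length(case_ids) || !length(ctrl_ids))
    stop("need at least one case and one control sample")
  cases <- expr$values[, case_ids, drop = FALSE]
  ctrls <- expr$values[, ctrl_ids, drop = FALSE]
  keep <- apply(ctrls, 1L, max) < threshold & apply(cases, 1L, min) > threshold
  case_mean <- rowMeans(cases)[keep]
  ctrl_mean <- rowMeans(ctrls)[keep]
  out <- data.frame(gene_id = rownames(expr$values)[keep],
                    fc = 2^(case_mean - ctrl_mean),
                    case_mean = unname(case_mean),
                    control_mean = unname(ctrl_mean),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fc, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d gene(s) at threshold %g\n",
              nrow(x), attr(x, "threshold")))
  NextMethod()
}

#' Linear fold change of a gene between case and control groups
#'
#' The antilog of the difference of group means on the log2 scale:
#' `2^(mean log2 case - mean log2 control)`. Always positive.
#'
#' @param expr an [expression_matrix()].
#' @param gene gene id(s) present in `expr`.
#' @return named numeric vector of fold changes.
#' @export
linear_fold_change <- function(expr, gene) {
  stopifnot(inherits(expr, "expr_matrix"))
  missing <- setdiff(gene, rownames(expr$values))
  if (length(missing)) stop("unknown gene(s): ",
                            paste(missing, collapse = ", "))
  case_ids <- group_samples(expr, "case")
  ctrl_ids <- group_samples(expr, "control")
  if (!length(case_ids) || !length(ctrl_ids))
    stop("need at least one case and one control sample")
  cm <- rowMeans(expr$values[gene, case_ids, drop = FALSE])
  km <- rowMeans(expr$values[gene, ctrl_ids, drop = FALSE])
  2^(cm - km)
}

#' Collapse probe-level rows to gene level by maximum mean
#'
#' For array data with several probes per gene, keeps the probe with the
#' largest mean expression across all samples (deterministic; ties broken by
#' probe id) and relabels the row with the gene symbol. Applied before
#' [consistency_filter()] when filtering at gene level.
#'
#' @param expr an [expression_matrix()] whose rows are probes.
#' @param probe_gene named character vector mapping probe id -> gene id for
#'   every row of `expr`.
#' @return an [expression_matrix()] with one row per gene.
#' @export
collapse_probes <- function(expr, probe_gene) {
  stopifnot(inherits(expr, "expr_matrix"))
  probes <- rownames(expr$values)
  if (!all(probes %in% names(probe_gene)))
    stop("probe_gene must map every probe of `expr`")
  genes <- unname(probe_gene[probes])
  means <- rowMeans(expr$values)
  ord <- order(genes, -means, probes)
  keep <- ord[!duplicated(genes[ord])]
  values <- expr$values[keep, , drop = FALSE]
  rownames(values) <- genes[keep]
  expression_matrix(values, expr$metadata)
}
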