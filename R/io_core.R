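#' Construct a validated expression matrix
#'
#' Container for log2 expression values (genes x samples) together with
#' per-sample metadata. This is the common currency of the screening and
#' co-expression stages: values are expected on the log2 scale so that the
#' consistency filter's sign convention ("below zero" = not expressed) and
#' antilog fold changes are meaningful.
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene ids, colnames sample ids. Must be finite, no missing values.
#' @param metadata data.frame with columns `sample_id`, `group` (one of
#'   `"case"`, `"control"`), and optionally `subtype` and `culture_id`.
#'   Every sample in `values` must be present; extra rows are dropped with
#'   a warning.
#' @return an object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `metadata` (data.frame aligned to the columns).
#' @export
expression_matrix <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite (missing values are not permitted)")
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(metadata)))
    stop("metadata must have columns `sample_id` and `group`")
  if (!"subtype" %in% names(metadata)) metadata$subtype <- NA_character_
  if (!"culture_id" %in% names(metadata)) metadata$culture_id <- NA_character_
  missing <- setdiff(colnames(values), metadata$sample_id)
  if (length(missing))
    stop("samples lacking metadata: ", paste(missing, collapse = ", "))
  extra <- setdiff(metadata$sample_id, colnames(values))
  if (length(extra)) {
    warning("metadata for unknown samples ignored: ",
            paste(extra, collapse = ", "))
    metadata <- metadata[metadata$sample_id %in% colnames(values), ,
                         drop = FALSE]
  }
  metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  bad <- !metadata$group %in% c("case", "control")
  if (any(bad))
    stop("group must be 'case' or 'control'; offending samples: ",
         paste(metadata$sample_id[bad], collapse = ", "))
  structure(list(values = values, metadata = metadata),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$metadata$group == "case"),
              sum(x$metadata$group == "control")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample metadata from TSV files
#'
#' The expression file is tab-delimited with gene ids in the first column
#' (header `gene_id`) and one column per sample. The metadata file has
#' columns `sample_id`, `group` and optionally `subtype`, `culture_id`.
#'
#' @param path expression TSV.
#' @param metadata_path metadata TSV.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("expression file needs gene_id plus >=1 sample")
  gene_ids <- tab[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                    dimnames = list(gene_ids, colnames(raw))))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing cell at gene %s, sample %s",
                 gene_ids[bad[1L]], colnames(raw)[bad[2L]]))
  }
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!"group" %in% names(meta))
    stop("metadata file lacks a `group` column")
  expression_matrix(values, meta)
}

#' Write an expression matrix (and optionally its metadata) to TSV
#'
#' Inverse of [read_expression()]: `read_expression(write_expression(x, ...))`
#' round-trips gene/sample ids bit-exactly and values to printed precision.
#'
#' @param x an `expr_matrix`.
#' @param path output TSV for the values.
#' @param metadata_path output TSV for the metadata (skipped if `NULL`).
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(x)
}

#' Subset an expression matrix by sample
#'
#' @param x an `expr_matrix`.
#' @param samples sample ids to keep.
#' @return an `expr_matrix` restricted to `samples`.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "expr_matrix"))
  missing <- setdiff(samples, colnames(x$values))
  if (length(missing)) stop("unknown samples: ", paste(missing, collapse = ", "))
  expression_matrix(x$values[, samples, drop = FALSE],
                    x$metadata[x$metadata$sample_id %in% samples, ,
                               drop = FALSE])
}

#' Group-wise sample ids of an expression matrix
#'
#' @param x an `expr_matrix`.
#' @param group `"case"` or `"control"`.
#' @return character vector of sample ids.
#' @export
group_samples <- function(x, group = c("case", "control")) {
  group <- match.arg(group)
  x$metadata$sample_id[x$metadata$group == group]
}
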