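#' Relative protein expression (RPE) from a band-intensity table
#'
#' Each band is background-subtracted and normalized to the
#' background-subtracted intensity of the corresponding loading-control
#' (beta-actin) band in the same lane:
#' `RPE = (band - band_bg) / (control - control_bg)`.
#' A band that falls below its local background (an absent protein) yields
#' RPE 0 with a QC flag rather than an error; a non-positive loading-control
#' net intensity is an error naming the sample, since nothing can be
#' normalized against it.
#'
#' @param b a band table with columns `protein_id`, `sample_id`, `band`,
#'   `band_bg`, `control`, `control_bg` (densitometry units, >= 0).
#' @return a protein x sample matrix of class `rpe_matrix`; clamped
#'   (below-background) entries are recorded in attribute `qc_clamped` as a
#'   data.frame of (protein_id, sample_id).
#' @export
rpe <- function(b) {
  need <- c("protein_id", "sample_id", "band", "band_bg", "control",
            "control_bg")
  missing <- setdiff(need, names(b))
  if (length(missing))
    stop("band table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(b$band < 0 | b$band_bg < 0 | b$control < 0 | b$control_bg < 0))
    stop("intensities must be non-negative")
  ctrl_net <- b$control - b$control_bg
  if (any(ctrl_net <= 0))
    stop("non-positive loading-control net intensity in sample(s): ",
         paste(unique(b$sample_id[ctrl_net <= 0]), collapse = ", "))
  band_net <- b$band - b$band_bg
  clamped <- band_net < 0
  band_net[clamped] <- 0
  vals <- band_net / ctrl_net
  proteins <- unique(b$protein_id)
  samples <- unique(b$sample_id)
  m <- matrix(NA_real_, length(proteins), length(samples),
              dimnames = list(proteins, samples))
  m[cbind(match(b$protein_id, proteins), match(b$sample_id, samples))] <- vals
  attr(m, "qc_clamped") <- data.frame(protein_id = b$protein_id[clamped],
                                      sample_id = b$sample_id[clamped],
                                      stringsAsFactors = FALSE)
  class(m) <- c("rpe_matrix", class(m))
  m
}

#' RNA-protein correlation of one gene across shared samples
#'
#' Pearson correlation between a per-sample mRNA profile (qPCR relative
#' expression) and the corresponding per-sample protein profile (RPE),
#' matched by sample id.
#'
#' @param qpcr_profile named numeric vector (sample -> relative expression).
#' @param rpe_profile named numeric vector (sample -> RPE).
#' @return the coefficient.
#' @export
rna_protein_r <- function(qpcr_profile, rpe_profile) {
  shared <- intersect(names(qpcr_profile), names(rpe_profile))
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  pearson_r(unname(qpcr_profile[shared]), unname(rpe_profile[shared]))
}

#' Mean and population SD of per-gene RNA-protein correlations
#'
#' Aggregates the per-gene coefficients of the packaged overview table over
#' a gene set, as the source summaries do (e.g. the nine-gene module's
#' "0.75 +/- 0.12"). The SD uses divisor n (population convention), which
#' is what reproduces the printed aggregate for the full 20-gene set. With
#' `signed = TRUE` the sign column is applied first (restoring the negative
#' coefficients of RAPGEF4, RHBDD1 and MCC that the table prints as
#' magnitudes).
#'
#' @param fixture a `table1_fixture` from [load_table1()].
#' @param gene_set gene ids (subset of the fixture); default all.
#' @param signed apply `correlation_sign` before aggregating.
#' @return named vector `c(mean, sd)`.
#' @export
summarize_correlations <- function(fixture, gene_set = fixture$gene_id,
                                   signed = FALSE) {
  stopifnot(inherits(fixture, "table1_fixture"))
  if (!length(gene_set)) stop("empty gene set")
  missing <- setdiff(gene_set, fixture$gene_id)
  if (length(missing))
    stop("gene(s) not in fixture: ", paste(missing, collapse = ", "))
  idx <- match(gene_set, fixture$gene_id)
  r <- if (signed) fixture$rna_protein_r_signed[idx]
       else fixture$rna_protein_r[idx]
  c(mean = mean(r), sd = sqrt(mean((r - mean(r))^2)))
}

#' Normalize sphere counts to the unit interval
#'
#' Rescales per-culture sphere counts so the control baseline maps to 0 and
#' the highest sphere-forming culture to 1, the convention used when assay
#' features are appended to a protein matrix for clustering.
#'
#' @param counts named numeric vector of per-culture sphere counts.
#' @param baseline control-culture count mapped to 0 (default 0).
#' @return rescaled vector in \[0, 1\].
#' @export
normalize_sphere_counts <- function(counts, baseline = 0) {
  if (max(counts) <= baseline) stop("no culture exceeds the baseline")
  pmax((counts - baseline) / (max(counts) - baseline), 0)
}

#' Cluster a protein RPE matrix with appended assay features
#'
#' Hierarchical co-expression clustering (Pearson distance, average
#' linkage) of protein rows, optionally with extra per-sample feature rows
#' appended — normalized sphere counts in \[0, 1\] and reciprocal
#' population doubling times, as in the targeted-proteomics view.
#'
#' @param rpe_matrix a protein x sample matrix (e.g. from [rpe()]).
#' @param extra_features optional named list/matrix of per-sample scalars;
#'   each element must cover exactly the samples of `rpe_matrix`.
#' @return list with elements `tree` (an `hclust`) and `distance`
#'   (the `dist_matrix` it was built from).
#' @export
targeted_proteomics_cluster <- function(rpe_matrix, extra_features = NULL) {
  m <- unclass(rpe_matrix)
  stopifnot(is.matrix(m), is.numeric(m))
  if (!is.null(extra_features)) {
    feat <- do.call(rbind, as.list(extra_features))
    if (is.null(rownames(feat)) && !is.null(names(extra_features)))
      rownames(feat) <- names(extra_features)
    if (!identical(sort(colnames(feat)), sort(colnames(m))))
      stop("extra features must share the sample set of the RPE matrix")
    m <- rbind(m, feat[, colnames(m), drop = FALSE])
  }
  d <- distance_matrix(m, axis = "genes", method = "pearson")
  list(tree = cluster_tree(d), distance = d)
}
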