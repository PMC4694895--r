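# internal: validate a Cq table and aggregate replicates to one Cq per
# (gene, sample); returns list(cq = gene x sample matrix, eff = named
# efficiencies, refs = reference gene ids, group = named sample groups).
# Passes a previously prepared object straight through, so batch callers
# pay the aggregation cost once.
prepare_cq <- function(t) {
  if (inherits(t, "cq_prepared")) return(t)
  need <- c("gene_id", "sample_id", "cq", "efficiency", "is_reference",
            "group")
  missing <- setdiff(need, names(t))
  if (length(missing))
    stop("Cq table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(t$cq <= 0)) stop("Cq values must be positive")
  if (any(t$efficiency <= 1 | t$efficiency > 2))
    stop("efficiencies must lie in (1, 2]")
  if (!any(t$is_reference)) stop("no reference gene present")
  eff <- tapply(t$efficiency, t$gene_id, unique)
  if (any(lengths(eff) != 1L))
    stop("efficiency must be constant within gene")
  grp <- tapply(t$group, t$sample_id, unique)
  if (any(lengths(grp) != 1L)) stop("sample mapped to several groups")
  agg <- tapply(t$cq, list(t$gene_id, t$sample_id), mean)
  structure(list(cq = agg,
                 eff = vapply(eff, identity, numeric(1L)),
                 refs = sort(unique(t$gene_id[t$is_reference])),
                 group = vapply(grp, identity, character(1L))),
            class = "cq_prepared")
}

# internal: per-sample composite log-expression score for a target gene,
# reference-normalized. The Pfaffl log-ratio between two sample groups is
# the difference of group means of this score.
cq_composite <- function(prep, gene) {
  if (!gene %in% rownames(prep$cq)) stop("gene not measured: ", gene)
  refs <- setdiff(prep$refs, gene)
  if (!length(refs)) stop("no reference gene available for ", gene)
  samples <- colnames(prep$cq)
  v <- prep$cq[gene, samples]
  if (anyNA(v)) {
    samples <- samples[!is.na(v)]
    v <- v[samples]
  }
  refmat <- prep$cq[refs, samples, drop = FALSE]
  if (anyNA(refmat))
    stop("reference gene(s) not measured in every sample for ", gene)
  u <- v * log(prep$eff[[gene]]) -
    colMeans(refmat * log(prep$eff[refs]))
  grp <- prep$group[samples]
  if (!all(c("case", "control") %in% grp))
    stop("gene ", gene, " lacks measurements in one group")
  list(u = u, grp = grp)
}

#' Efficiency-corrected relative expression ratio (Pfaffl)
#'
#' The relative expression of a target gene in the case group versus the
#' control group, corrected for amplification efficiency and normalized to
#' the geometric mean of the reference genes:
#' `ratio = E_target^dCq_target / geomean_ref(E_ref^dCq_ref)` with
#' `dCq = mean Cq(control) - mean Cq(case)`. Replicates are averaged to one
#' Cq per (gene, sample) first. With all efficiencies equal to 2 this
#' reduces to the classical 2^-ddCt quantity.
#'
#' @param t a Cq table (see [simulate_cq()] for the column contract).
#' @param gene target gene id.
#' @return the positive ratio.
#' @export
pfaffl_ratio <- function(t, gene) {
  prep <- prepare_cq(t)
  comp <- cq_composite(prep, gene)
  # dCq enters with a minus sign through the composite (lower Cq = more
  # template), so control-minus-case on u is the log ratio directly
  exp(mean(comp$u[comp$grp == "control"]) -
        mean(comp$u[comp$grp == "case"]))
}

#' Fixed-reallocation randomization test for a relative expression ratio
#'
#' Two-sided significance of the [pfaffl_ratio()]: case/control labels are
#' reallocated over the samples with group sizes fixed, the
#' reference-normalized log ratio is recomputed for every allocation, and
#' the p-value is the proportion of allocations whose absolute log ratio is
#' at least the observed one. When the number of distinct allocations is at
#' most `iterations` they are enumerated exhaustively (the observed
#' allocation is then one of them); otherwise `iterations` random
#' reallocations are drawn and the observed allocation is added to both
#' numerator and denominator, so p is never 0.
#'
#' @param t a Cq table.
#' @param gene target gene id.
#' @param iterations maximum allocations to evaluate (default 2000).
#' @param seed seed for the Monte-Carlo branch.
#' @return the p-value, in (0, 1].
#' @export
reallocation_test <- function(t, gene, iterations = 2000L, seed = 1L) {
  prep <- prepare_cq(t)
  comp <- cq_composite(prep, gene)
  u <- comp$u
  n <- length(u)
  n_case <- sum(comp$grp == "case")
  if (n_case < 2L || n - n_case < 2L)
    stop("need at least 2 samples per group")
  obs <- abs(mean(u[comp$grp == "control"]) - mean(u[comp$grp == "case"]))
  tot <- sum(u)
  n_alloc <- choose(n, n_case)
  eps <- 1e-12
  if (n_alloc <= iterations) {
    idx <- utils::combn(n, n_case)
    cs <- colSums(matrix(u[idx], nrow = n_case))
    stats <- abs((tot - cs) / (n - n_case) - cs / n_case)
    mean(stats >= obs - eps)
  } else {
    with_seed(seed, {
      hits <- 0L
      for (i in seq_len(iterations)) {
        a <- sample.int(n, n_case)
        cs <- sum(u[a])
        s <- abs((tot - cs) / (n - n_case) - cs / n_case)
        if (s >= obs - eps) hits <- hits + 1L
      }
      (hits + 1L) / (iterations + 1L)
    })
  }
}

#' Regulation call from a ratio and its p-value
#'
#' `UP` if ratio > 1 and p < alpha, `DR` if ratio < 1 and p < alpha,
#' otherwise `NS`. Vectorized.
#'
#' @param ratio positive ratio(s) from [pfaffl_ratio()].
#' @param p p-value(s) from [reallocation_test()].
#' @param alpha significance level (default 0.05).
#' @return character vector of calls.
#' @export
call_regulation <- function(ratio, p, alpha = 0.05) {
  stopifnot(length(ratio) == length(p), all(ratio > 0),
            all(p > 0 & p <= 1))
  ifelse(p < alpha, ifelse(ratio > 1, "UP", ifelse(ratio < 1, "DR", "NS")),
         "NS")
}

#' Relative expression of every target gene in a Cq table
#'
#' Runs [pfaffl_ratio()], [reallocation_test()] and [call_regulation()] for
#' each non-reference gene.
#'
#' @param t a Cq table.
#' @param genes target genes (default: every non-reference gene).
#' @param iterations,seed passed to [reallocation_test()].
#' @param alpha passed to [call_regulation()].
#' @return a data.frame of class `relative_expression` with columns
#'   `gene_id`, `ratio`, `p`, `call`.
#' @export
relative_expression <- function(t, genes = NULL, iterations = 2000L,
                                seed = 1L, alpha = 0.05) {
  prep <- prepare_cq(t)
  if (is.null(genes)) genes <- sort(setdiff(rownames(prep$cq), prep$refs))
  ratio <- vapply(genes, function(g) pfaffl_ratio(prep, g), numeric(1L))
  p <- vapply(seq_along(genes), function(i)
    reallocation_test(prep, genes[i], iterations = iterations,
                      seed = seed + i), numeric(1L))
  out <- data.frame(gene_id = genes, ratio = unname(ratio), p = p,
                    call = call_regulation(unname(ratio), p, alpha),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("relative_expression", "data.frame")
  out
}
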