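#' Packaged per-gene overview of the 20-gene candidate set
#'
#' The published overview table for the 20 genes that passed the consistency
#' filter: linear fold changes from microarray, qPCR and western blot, the
#' per-assay regulation calls (UP/DR/NS), and the RNA-protein Pearson
#' coefficient for each gene. Coefficients are stored as printed magnitudes
#' in `rna_protein_r` together with a `correlation_sign` column: the source
#' text reports a *negative* RNA-protein correlation for RAPGEF4, RHBDD1 and
#' MCC, while the table prints magnitudes only, so the sign is carried
#' separately and `rna_protein_r_signed = correlation_sign * rna_protein_r`.
#'
#' Gene ids are canonical upper-case symbols; slash-separated aliases from
#' the source (e.g. DLG7/DLGAP5/HURP) are kept in `aliases`,
#' semicolon-separated.
#'
#' @return a data.frame of class `table1_fixture` with 20 rows.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_gene_overview.csv",
                      package = "gsctargets", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$rna_protein_r_signed <- tab$correlation_sign * tab$rna_protein_r
  stopifnot(nrow(tab) == 20L, !anyDuplicated(tab$gene_id),
            all(tab$rna_protein_r >= 0 & tab$rna_protein_r <= 1))
  class(tab) <- c("table1_fixture", "data.frame")
  tab
}

#' Packaged highlighted protein-protein interactions
#'
#' The published table of highlighted interactions among the candidate-gene
#' products, pathway reporters (MTOR, STAT3, DLL3, EGFR, SOX2, NF1, ...) and
#' the regulators BMI1 and HIF1A, as extracted from a literature-curated
#' interaction database. Each record is a protein pair with a `direct`
#' flag ("yes" when the two bind directly) and a `via` list of intermediary
#' proteins mediating one-step indirect paths (semicolon-separated; may be
#' empty for direct pairs, and direct pairs may also list intermediaries).
#' Rows grouped in the source (e.g. one hub against a bracketed partner
#' list) are stored one record per partner; duplicated source rows are kept
#' as printed and deduplicated at graph-building time.
#'
#' @return a data.frame of class `table2_fixture` with columns `section`,
#'   `protein_a`, `protein_b`, `direct`, `via`.
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2_interactions.csv",
                      package = "gsctargets", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = character())
  stopifnot(all(nzchar(tab$protein_a)), all(nzchar(tab$protein_b)),
            all(tab$direct %in% c("yes", "no")))
  class(tab) <- c("table2_fixture", "data.frame")
  tab
}

#' Intermediary list of a fixture record
#'
#' @param via semicolon-separated `via` strings.
#' @return list of character vectors (empty vector for empty strings).
#' @export
via_list <- function(via) {
  lapply(strsplit(via, ";", fixed = TRUE),
         function(v) v[nzchar(v)])
}

#' Expand the highlighted-interaction table into an edge list
#'
#' Direct records contribute the edge (a, b); every intermediary x in a
#' record's `via` list contributes the two edges (a, x) and (x, b). Records
#' that are both direct and mediated contribute all three kinds of edge.
#'
#' @param tab a `table2_fixture` (default: the packaged one).
#' @return a data.frame with columns `node_a`, `node_b`, `type`, `evidence`
#'   suitable for [build_graph()]. `evidence` is `"direct"` for printed
#'   direct pairs and `"intermediary"` for expanded indirect edges.
#' @export
table2_edges <- function(tab = load_table2()) {
  vias <- via_list(tab$via)
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    a <- tab$protein_a[i]; b <- tab$protein_b[i]
    rows <- NULL
    if (tab$direct[i] == "yes")
      rows <- data.frame(node_a = a, node_b = b, evidence = "direct",
                         stringsAsFactors = FALSE)
    v <- vias[[i]]
    if (length(v))
      rows <- rbind(rows,
                    data.frame(node_a = c(rep(a, length(v)), v),
                               node_b = c(v, rep(b, length(v))),
                               evidence = "intermediary",
                               stringsAsFactors = FALSE))
    out[[i]] <- rows
  }
  edges <- do.call(rbind, out)
  edges$type <- "protein-protein"
  edges[, c("node_a", "node_b", "type", "evidence")]
}

#' Interaction graph of the packaged highlighted-interaction table
#'
#' Convenience wrapper: [table2_edges()] piped into [build_graph()]. This is
#' the canonical test graph for the common-interactant queries.
#'
#' @return an `interaction_graph`.
#' @export
load_table2_graph <- function() {
  build_graph(table2_edges(load_table2()))
}
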