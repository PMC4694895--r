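Package: gsctargets
Title: Candidate Therapeutic-Target Discovery in Glioblastoma Stem Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for screening candidate therapeutic targets in
    glioblastoma stem cells (GSCs) against neural stem cell (NSC) controls.
    Implements a strict consistency filter on log2 expression matrices,
    Pearson-distance hierarchical co-expression modules with PCA overviews,
    efficiency-corrected (Pfaffl) qPCR quantification with a
    fixed-reallocation randomization test, western-blot relative protein
    expression (RPE) with RNA-protein correlation summaries, growth-assay
    arithmetic (population doubling time, sphere assays), module-based
    survival stratification with a Gehan-Breslow-Wilcoxon weighted log-rank
    test, univariate logistic screening with Benjamini-Hochberg FDR control,
    and common-interactant queries on molecular-interaction graphs. Ships
    seeded generators that plant recoverable structure in every input type
    so the whole pipeline is testable without external downloads, plus the
    published per-gene summary table and highlighted-interaction table as
    packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
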