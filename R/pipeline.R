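#' Pipeline configuration
#'
#' Settings for [run_pipeline()]: one master seed (stage seeds are derived
#' from it, so stages are independently reproducible), the analysis
#' thresholds, stage toggles, and an output directory.
#'
#' @param sim a [sim_config()] describing the inputs to generate; its seed
#'   is overridden by `seed`.
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory (`NULL`: nothing written to disk).
#' @param threshold consistency-filter threshold (log2).
#' @param alpha significance level for qPCR regulation calls.
#' @param q FDR level for the logistic screen.
#' @param k number of co-expression modules / survival strata.
#' @param stages character vector of stages to run, a subset of
#'   `c("screen", "cluster", "qpcr", "proteomics", "survival", "network")`.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), seed = 1L, out_dir = NULL,
                            threshold = 0, alpha = 0.05, q = 0.10, k = 3L,
                            stages = c("screen", "cluster", "qpcr",
                                       "proteomics", "survival", "network")) {
  known <- c("screen", "cluster", "qpcr", "proteomics", "survival",
             "network")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, seed = as.integer(seed), out_dir = out_dir,
                 threshold = threshold, alpha = alpha, q = q,
                 k = as.integer(k), stages = stages),
            class = "pipeline_config")
}

#' Run the candidate-target discovery pipeline end to end
#'
#' Generates (or is handed) the inputs, then runs the enabled stages in
#' order: consistency screen, co-expression clustering, qPCR relative
#' expression with randomization tests, western RPE quantification,
#' module-based survival stratification with the Gehan-Breslow-Wilcoxon
#' comparison, and interaction-network queries. Deterministic given the
#' config seed. A stage failure halts with an error naming the stage;
#' outputs of completed stages are preserved in the output directory.
#'
#' @param cfg a [pipeline_config()].
#' @return a list of class `pipeline_report` with one element per enabled
#'   stage (and `inputs` holding the simulated data).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(name, tab) {
    if (!is.null(cfg$out_dir))
      utils::write.table(tab, file.path(cfg$out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  report <- list(seed = cfg$seed)
  expr <- run_stage("simulate", simulate_expression(cfg$sim))
  report$inputs <- list(expression = expr)

  if ("screen" %in% cfg$stages) {
    cand <- run_stage("screen", consistency_filter(expr, cfg$threshold))
    emit("candidates", cand)
    report$screen <- cand
  }
  if ("cluster" %in% cfg$stages) {
    report$cluster <- run_stage("cluster", {
      genes <- if (!is.null(report$screen) && nrow(report$screen) >= cfg$k)
        report$screen$gene_id else rownames(expr$values)
      sub <- expr$values[genes, , drop = FALSE]
      d <- distance_matrix(sub, axis = "genes")
      modules <- cut_modules(cluster_tree(d), k = min(cfg$k, nrow(sub)))
      emit("modules", data.frame(gene_id = names(modules),
                                 module = unclass(modules)))
      list(modules = modules, pca = pca_overview(expr))
    })
  }
  if ("qpcr" %in% cfg$stages) {
    cq <- run_stage("qpcr", simulate_cq(cfg$sim))
    res <- run_stage("qpcr",
                     relative_expression(cq, seed = cfg$seed,
                                         alpha = cfg$alpha))
    emit("qpcr", res)
    report$qpcr <- res
    report$inputs$cq <- cq
  }
  if ("proteomics" %in% cfg$stages) {
    report$proteomics <- run_stage("proteomics", {
      bands <- simulate_bands(cfg$sim)
      report$inputs$bands <- bands
      m <- rpe(bands)
      emit("rpe", data.frame(protein_id = rownames(m), unclass(m),
                             check.names = FALSE))
      case_mean <- rowMeans(m[, unique(bands$sample_id[bands$group == "case"]),
                              drop = FALSE])
      ctrl_mean <- rowMeans(m[, unique(bands$sample_id[bands$group == "control"]),
                              drop = FALSE])
      list(rpe = m, fold_change = case_mean / ctrl_mean)
    })
  }
  if ("survival" %in% cfg$stages) {
    report$survival <- run_stage("survival", {
      tab <- simulate_survival(cfg$sim)
      report$inputs$survival <- tab
      strat <- stratify(tab, cfg$sim$survival$module_genes, k = cfg$k)
      cmp <- survival_compare(tab, strat, c("high", "low"))
      emit("stratification", data.frame(patient_id = names(strat),
                                        group = unclass(strat)))
      list(stratification = strat, comparison = cmp)
    })
  }
  if ("network" %in% cfg$stages) {
    report$network <- run_stage("network", {
      g <- load_table2_graph()
      list(graph = g,
           egfr_pbk = common_interactants(g, "EGFR", "PBK"),
           stat3_ezh2 = common_interactants(g, "STAT3", "EZH2"),
           hubs = hubs(g))
    })
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("candidate-target discovery pipeline report\n")
  cat(sprintf("  seed: %d\n", x$seed))
  if (!is.null(x$screen))
    cat(sprintf("  screen: %d candidate gene(s)\n", nrow(x$screen)))
  if (!is.null(x$cluster))
    cat(sprintf("  cluster: %d module(s)\n",
                length(unique(unclass(x$cluster$modules)))))
  if (!is.null(x$qpcr))
    cat(sprintf("  qpcr: %d UP, %d DR, %d NS\n",
                sum(x$qpcr$call == "UP"), sum(x$qpcr$call == "DR"),
                sum(x$qpcr$call == "NS")))
  if (!is.null(x$proteomics))
    cat(sprintf("  proteomics: %d protein(s) quantified\n",
                nrow(x$proteomics$rpe)))
  if (!is.null(x$survival))
    cat(sprintf("  survival: medians high = %s, low = %s days; GBW p = %.4g\n",
                format(x$survival$comparison$medians[["high"]]),
                format(x$survival$comparison$medians[["low"]]),
                x$survival$comparison$test$p.value))
  if (!is.null(x$network))
    cat(sprintf("  network: EGFR-PBK %d, STAT3-EZH2 %d common interactants; %d hub(s)\n",
                length(x$network$egfr_pbk), length(x$network$stat3_ezh2),
                length(x$network$hubs)))
  invisible(x)
}
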