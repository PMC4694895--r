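#' Evaluate code with a local, named RNG seed
#'
#' All generators thread randomness through this helper: Mersenne-Twister
#' with inversion normals, seeded explicitly, with the caller's RNG state
#' restored afterwards. Identical seed implies identical output.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. The defaults emulate
#' the study design this package is built around: a 9-case (GSC) / 5-control
#' (NSC) log2 expression matrix with 20 planted consistently-expressed genes
#' at log2 means +2 (case) / -2 (control) over a mean-zero background,
#' qPCR crossing-point tables whose planted fold changes are the published
#' qPCR fold changes of the 20-gene set, western band tables planting the
#' published protein fold changes, and a 200-patient survival table with a
#' planted hazard difference between high and low module-expression groups.
#'
#' @param n_genes number of genes in the expression universe.
#' @param n_case,n_control sample counts per group.
#' @param planted_genes ids of the planted consistent genes.
#' @param case_mean,control_mean log2 group means for planted genes.
#' @param background_mean log2 mean for non-planted genes.
#' @param noise_sd log2 within-group SD for expression values.
#' @param seed integer seed; threads through every generator.
#' @param modules optional list of co-expression modules, each a list with
#'   elements `id`, `genes` and `rho` (within-module correlation in \[0, 1)).
#' @param qpcr a [qpcr_spec()].
#' @param western a [western_spec()].
#' @param survival a [survival_spec()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, n_case = 9L, n_control = 5L,
                       planted_genes = sprintf("TG%02d", 1:20),
                       case_mean = 2, control_mean = -2,
                       background_mean = 0, noise_sd = 0.5,
                       seed = 1L, modules = NULL,
                       qpcr = qpcr_spec(), western = western_spec(),
                       survival = survival_spec()) {
  stopifnot(n_genes >= length(planted_genes), n_case >= 1L, n_control >= 1L,
            noise_sd >= 0, !anyDuplicated(planted_genes))
  for (m in modules) {
    stopifnot(is.character(m$genes), length(m$genes) >= 2L,
              m$rho >= 0, m$rho < 1)
  }
  structure(list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 planted_genes = planted_genes, case_mean = case_mean,
                 control_mean = control_mean,
                 background_mean = background_mean, noise_sd = noise_sd,
                 seed = as.integer(seed), modules = modules, qpcr = qpcr,
                 western = western, survival = survival),
            class = "sim_config")
}

#' qPCR generator specification
#'
#' @param fold_changes named vector of planted linear case/control expression
#'   ratios for the target genes. Default: the published qPCR fold changes of
#'   the 20-gene candidate set.
#' @param reference_genes ids of reference (housekeeping) genes, planted at
#'   ratio 1.
#' @param efficiency amplification factor per cycle, in (1, 2]; a single
#'   value or a vector named by gene for per-gene overrides.
#' @param baseline_cq control-group crossing point for every gene (cycles).
#' @param n_replicates technical replicates per (gene, sample).
#' @param replicate_sd SD of replicate-level Cq noise (cycles).
#' @param sample_offset_sd SD of per-sample Cq offsets (cycles), emulating
#'   loading/RNA-input differences that reference normalization removes.
#' @return a list of class `qpcr_spec`.
#' @export
qpcr_spec <- function(fold_changes = NULL,
                      reference_genes = c("ACTB", "GAPDH"),
                      efficiency = 2, baseline_cq = 24,
                      n_replicates = 3L, replicate_sd = 0.15,
                      sample_offset_sd = 0.25) {
  stopifnot(all(efficiency > 1), all(efficiency <= 2), baseline_cq > 0,
            length(reference_genes) >= 1L, n_replicates >= 1L,
            replicate_sd >= 0, sample_offset_sd >= 0)
  structure(list(fold_changes = fold_changes,
                 reference_genes = reference_genes, efficiency = efficiency,
                 baseline_cq = baseline_cq,
                 n_replicates = as.integer(n_replicates),
                 replicate_sd = replicate_sd,
                 sample_offset_sd = sample_offset_sd),
            class = "qpcr_spec")
}

#' Western-blot generator specification
#'
#' @param rpe_case named vector of planted case-group relative protein
#'   expression (RPE) values. Default: the published western fold changes of
#'   the 20-gene candidate set.
#' @param rpe_control control-group RPE (single value recycled).
#' @param noise_sdlog SD of multiplicative lognormal band noise.
#' @param background additive local background (densitometry units).
#' @param control_intensity net loading-control band intensity.
#' @return a list of class `western_spec`.
#' @export
western_spec <- function(rpe_case = NULL, rpe_control = 1,
                         noise_sdlog = 0.2, background = 100,
                         control_intensity = 5000) {
  stopifnot(rpe_control > 0, noise_sdlog >= 0, background >= 0,
            control_intensity > 0)
  structure(list(rpe_case = rpe_case, rpe_control = rpe_control,
                 noise_sdlog = noise_sdlog, background = background,
                 control_intensity = control_intensity),
            class = "western_spec")
}

#' Survival generator specification
#'
#' Exponential event times with a group-specific hazard: patients are split
#' evenly into planted "low" and "high" module-expression groups; the low
#' group has median survival `baseline_median_days` and the high group's
#' hazard is multiplied by `hazard_multiplier`. Module-gene expression is
#' drawn around +/- `expr_shift` so that stratification can recover the
#' planted groups.
#'
#' @param n_patients total patients (split evenly, remainder to "low").
#' @param baseline_median_days median survival of the planted low group.
#' @param hazard_multiplier hazard ratio of high vs low group.
#' @param censoring_rate expected fraction of censored records in each group.
#' @param module_genes gene ids whose expression carries the planted signal;
#'   default: the nine-gene co-expression module of the candidate set.
#' @param expr_shift absolute log2 shift of module genes in each group.
#' @param expr_sd log2 SD of module-gene expression around its group mean.
#' @return a list of class `survival_spec`.
#' @export
survival_spec <- function(n_patients = 200L, baseline_median_days = 383,
                          hazard_multiplier = 2, censoring_rate = 0.2,
                          module_genes = c("CENPA", "DLG7", "PBK", "CDC6",
                                           "KIF15", "KIF18A", "EZH2",
                                           "DEPDC1", "HMMR"),
                          expr_shift = 1, expr_sd = 0.5) {
  stopifnot(n_patients >= 2L, baseline_median_days > 0,
            hazard_multiplier > 0, censoring_rate >= 0, censoring_rate < 1,
            length(module_genes) >= 1L, expr_sd >= 0)
  structure(list(n_patients = as.integer(n_patients),
                 baseline_median_days = baseline_median_days,
                 hazard_multiplier = hazard_multiplier,
                 censoring_rate = censoring_rate,
                 module_genes = module_genes, expr_shift = expr_shift,
                 expr_sd = expr_sd),
            class = "survival_spec")
}

# stage-specific seeds derived from the one config seed, kept below 2^31
derive_seed <- function(seed, stage) {
  offsets <- c(expression = 101L, cq = 211L, bands = 307L,
               survival = 401L, edges = 503L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Simulate a log2 expression matrix with planted structure
#'
#' Planted genes are drawn around `case_mean` in case samples and
#' `control_mean` in control samples so that, in expectation, every control
#' value is below zero and every case value above zero; background genes are
#' drawn around `background_mean`. Members of a module share a per-sample
#' latent factor: each value is
#' `mean + noise_sd * (sqrt(rho) * f_s + sqrt(1 - rho) * e)`, giving
#' within-module pairwise correlation `rho` and marginal SD `noise_sd`.
#'
#' @param config a [sim_config()].
#' @return an [expression_matrix()]; the planted gene ids are attached as
#'   attribute `planted`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  module_genes <- unique(unlist(lapply(config$modules, `[[`, "genes")))
  named <- union(config$planted_genes, module_genes)
  if (length(named) > config$n_genes)
    stop("planted/module genes exceed the gene universe")
  n_bg <- config$n_genes - length(named)
  genes <- c(named, if (n_bg) sprintf("BG%05d", seq_len(n_bg)))
  samples <- c(sprintf("GSC%02d", seq_len(config$n_case)),
               sprintf("NSC%02d", seq_len(config$n_control)))
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))

  mu <- matrix(config$background_mean, length(genes), length(samples),
               dimnames = list(genes, samples))
  mu[config$planted_genes, group == "case"] <- config$case_mean
  mu[config$planted_genes, group == "control"] <- config$control_mean

  values <- with_seed(derive_seed(config$seed, "expression"), {
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
    for (m in config$modules) {
      f <- stats::rnorm(ncol(mu))
      idx <- match(m$genes, genes)
      eps[idx, ] <- sqrt(m$rho) * rep(f, each = length(idx)) +
        sqrt(1 - m$rho) * eps[idx, , drop = FALSE]
    }
    mu + config$noise_sd * eps
  })
  meta <- data.frame(sample_id = samples, group = group,
                     subtype = NA_character_,
                     culture_id = samples, stringsAsFactors = FALSE)
  out <- expression_matrix(values, meta)
  attr(out, "planted") <- config$planted_genes
  out
}

#' Simulate a qPCR crossing-point table
#'
#' Control-group Cq sits at `baseline_cq`; case-group Cq is lowered by
#' `log(fold_change) / log(E)` cycles so that the efficiency-corrected
#' ratio ([pfaffl_ratio()]) recovers the planted fold change. Per-sample
#' offsets are added to every gene of a sample (and cancel through the
#' reference genes); replicate noise is added per measurement.
#'
#' @param config a [sim_config()]; uses its `qpcr` spec and group sizes.
#' @return a data.frame of class `cq_table` with columns `gene_id`,
#'   `sample_id`, `replicate`, `cq`, `efficiency`, `is_reference`, `group`;
#'   planted fold changes attached as attribute `planted`.
#' @export
simulate_cq <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$qpcr
  fc <- spec$fold_changes
  if (is.null(fc)) {
    t1 <- load_table1()
    fc <- stats::setNames(t1$qpcr_fc, t1$gene_id)
  }
  if (is.null(names(fc)) || !all(nzchar(names(fc))))
    stop("qPCR fold changes must be named by gene")
  genes <- c(names(fc), spec$reference_genes)
  ratios <- c(fc, stats::setNames(rep(1, length(spec$reference_genes)),
                                  spec$reference_genes))
  eff <- rep(spec$efficiency, length.out = length(genes))
  if (!is.null(names(spec$efficiency)))
    eff <- ifelse(genes %in% names(spec$efficiency),
                  spec$efficiency[genes], 2)
  names(eff) <- genes
  samples <- c(sprintf("GSC%02d", seq_len(config$n_case)),
               sprintf("NSC%02d", seq_len(config$n_control)))
  group <- stats::setNames(rep(c("case", "control"),
                               c(config$n_case, config$n_control)), samples)

  tab <- with_seed(derive_seed(config$seed, "cq"), {
    offsets <- stats::setNames(
      stats::rnorm(length(samples), 0, spec$sample_offset_sd), samples)
    grid <- expand.grid(gene_id = genes, sample_id = samples,
                        replicate = seq_len(spec$n_replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    shift <- ifelse(group[grid$sample_id] == "case",
                    log(ratios[grid$gene_id]) / log(eff[grid$gene_id]), 0)
    grid$cq <- spec$baseline_cq - shift + offsets[grid$sample_id] +
      stats::rnorm(nrow(grid), 0, spec$replicate_sd)
    grid
  })
  tab$efficiency <- eff[tab$gene_id]
  tab$is_reference <- tab$gene_id %in% spec$reference_genes
  tab$group <- unname(group[tab$sample_id])
  if (any(tab$cq <= 0)) stop("degenerate spec: non-positive Cq generated")
  class(tab) <- c("cq_table", "data.frame")
  attr(tab, "planted") <- fc
  tab
}

#' Simulate a western-blot band-intensity table
#'
#' Band intensity is `true RPE x loading-control net intensity x lognormal
#' noise + background`; the loading-control lane is `control_intensity +
#' background` with the same local background, so that [rpe()] inverts the
#' generator exactly at zero noise.
#'
#' @param config a [sim_config()]; uses its `western` spec and group sizes.
#' @return a data.frame of class `band_table` with columns `protein_id`,
#'   `sample_id`, `band`, `band_bg`, `control`, `control_bg`, `group`;
#'   planted case-group RPE attached as attribute `planted`.
#' @export
simulate_bands <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$western
  rpe_case <- spec$rpe_case
  if (is.null(rpe_case)) {
    t1 <- load_table1()
    rpe_case <- stats::setNames(t1$western_fc, t1$gene_id)
  }
  if (is.null(names(rpe_case)) || !all(nzchar(names(rpe_case))))
    stop("planted RPE values must be named by protein")
  proteins <- names(rpe_case)
  samples <- c(sprintf("GSC%02d", seq_len(config$n_case)),
               sprintf("NSC%02d", seq_len(config$n_control)))
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))

  grid <- expand.grid(protein_id = proteins, sample_id = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$group <- group[match(grid$sample_id, samples)]
  true_rpe <- ifelse(grid$group == "case",
                     rpe_case[grid$protein_id], spec$rpe_control)
  grid <- with_seed(derive_seed(config$seed, "bands"), {
    noise <- exp(stats::rnorm(nrow(grid), 0, spec$noise_sdlog))
    grid$band <- true_rpe * spec$control_intensity * noise + spec$background
    grid
  })
  grid$band_bg <- spec$background
  grid$control <- spec$control_intensity + spec$background
  grid$control_bg <- spec$background
  out <- grid[, c("protein_id", "sample_id", "band", "band_bg",
                  "control", "control_bg", "group")]
  class(out) <- c("band_table", "data.frame")
  attr(out, "planted") <- rpe_case
  out
}

#' Simulate a survival table with a planted hazard difference
#'
#' Event times are exponential with hazard `log(2) / baseline_median_days`
#' in the planted low group and `hazard_multiplier` times that in the high
#' group. Censoring times are exponential with rate chosen so the expected
#' censored fraction equals `censoring_rate`. Module-gene expression is
#' `N(+expr_shift, expr_sd)` for high patients and `N(-expr_shift, expr_sd)`
#' for low patients; subtype labels are drawn with cohort-like frequencies.
#'
#' @param config a [sim_config()]; uses its `survival` spec.
#' @return a data.frame of class `survival_table` with columns `patient_id`,
#'   `time_days`, `event`, `subtype`, then one column per module gene; the
#'   planted group is attached both as attribute `planted` and as column
#'   `planted_group`.
#' @export
simulate_survival <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$survival
  n <- spec$n_patients
  if (n < 2L) stop("degenerate spec: need at least two patients")
  n_high <- n %/% 2L
  planted <- rep(c("low", "high"), c(n - n_high, n_high))
  h_low <- log(2) / spec$baseline_median_days
  hazard <- ifelse(planted == "high", h_low * spec$hazard_multiplier, h_low)
  subtypes <- c("classical", "mesenchymal", "proneural", "neural")
  subtype_w <- c(54, 58, 57, 33) / 202

  with_seed(derive_seed(config$seed, "survival"), {
    t_event <- stats::rexp(n, hazard)
    if (spec$censoring_rate > 0) {
      h_cens <- hazard * spec$censoring_rate / (1 - spec$censoring_rate)
      t_cens <- stats::rexp(n, h_cens)
    } else t_cens <- rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    expr <- matrix(stats::rnorm(n * length(spec$module_genes),
                                mean = ifelse(planted == "high",
                                              spec$expr_shift,
                                              -spec$expr_shift),
                                sd = spec$expr_sd),
                   nrow = n, dimnames = list(NULL, spec$module_genes))
    tab <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                      time_days = time, event = event,
                      subtype = sample(subtypes, n, replace = TRUE,
                                       prob = subtype_w),
                      planted_group = planted, stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(expr))
    class(tab) <- c("survival_table", "data.frame")
    attr(tab, "planted") <- planted
    tab
  })
}

#' Simulate a typed molecular-interaction edge list
#'
#' Endpoints are drawn with Zipf-like weights (weight of node i proportional
#' to 1 / rank^0.8), producing a right-skewed degree distribution with a few
#' hub-like nodes, as in curated interaction databases.
#'
#' @param n_nodes,n_edges graph size.
#' @param seed integer seed.
#' @return a data.frame with columns `node_a`, `node_b`, `type`, `evidence`
#'   (no self-loops; duplicates possible, deduplicated by [build_graph()]).
#' @export
simulate_edges <- function(n_nodes, n_edges, seed = 1L) {
  stopifnot(n_nodes >= 2L, n_edges >= 1L)
  nodes <- sprintf("N%04d", seq_len(n_nodes))
  w <- 1 / seq_len(n_nodes)^0.8
  types <- c("protein-protein", "protein-DNA", "protein-RNA", "genetic")
  with_seed(seed, {
    a <- sample(nodes, 4L * n_edges, replace = TRUE, prob = w)
    b <- sample(nodes, 4L * n_edges, replace = TRUE, prob = w)
    keep <- which(a != b)[seq_len(n_edges)]
    if (anyNA(keep)) stop("could not draw enough non-loop edges")
    data.frame(node_a = a[keep], node_b = b[keep],
               type = sample(types, n_edges, replace = TRUE,
                             prob = c(0.7, 0.15, 0.1, 0.05)),
               evidence = "simulated", stringsAsFactors = FALSE)
  })
}

#' Write every simulated input (plus a manifest of planted truths) to disk
#'
#' Emits the TSV/CSV dialects the package readers consume, together with a
#' plain key=value manifest recording the planted parameters, so external
#' harnesses can check recovery.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- simulate_expression(config)
  write_expression(expr, file.path(dir, "expression.tsv"),
                   file.path(dir, "samples.tsv"))
  utils::write.csv(simulate_cq(config), file.path(dir, "cq.csv"),
                   row.names = FALSE)
  utils::write.csv(simulate_bands(config), file.path(dir, "bands.csv"),
                   row.names = FALSE)
  utils::write.table(simulate_survival(config),
                     file.path(dir, "survival.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- c(
    sprintf("seed=%d", config$seed),
    sprintf("planted_genes=%s", paste(config$planted_genes, collapse = ";")),
    sprintf("case_mean=%g", config$case_mean),
    sprintf("control_mean=%g", config$control_mean),
    sprintf("noise_sd=%g", config$noise_sd),
    sprintf("survival_hazard_multiplier=%g",
            config$survival$hazard_multiplier),
    sprintf("survival_baseline_median_days=%g",
            config$survival$baseline_median_days))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
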