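# Independent oracles: deliberately naive (loop-based, direct-formula)
# re-implementations used to cross-check the package's vectorized paths.

# exhaustive per-gene predicate for the consistency filter
brute_consistency <- function(values, case_ids, ctrl_ids, threshold = 0) {
  sel <- character()
  for (g in rownames(values)) {
    ok <- TRUE
    for (s in ctrl_ids) if (!(values[g, s] < threshold)) ok <- FALSE
    for (s in case_ids) if (!(values[g, s] > threshold)) ok <- FALSE
    if (ok) sel <- c(sel, g)
  }
  sel
}

# double-loop Pearson distance
naive_distance <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- 1 - stats::cor(m[i, ], m[j, ])
  diag(d) <- 0
  d
}

# direct-formula efficiency-corrected ratio (replicates averaged first)
naive_pfaffl <- function(tab, gene) {
  agg <- stats::aggregate(cq ~ gene_id + sample_id, tab, mean)
  agg$group <- tab$group[match(agg$sample_id, tab$sample_id)]
  eff_of <- function(g) unique(tab$efficiency[tab$gene_id == g])
  dcq <- function(g) {
    x <- agg[agg$gene_id == g, ]
    mean(x$cq[x$group == "control"]) - mean(x$cq[x$group == "case"])
  }
  refs <- unique(tab$gene_id[tab$is_reference])
  refs <- setdiff(refs, gene)
  gm <- prod(vapply(refs, function(r) eff_of(r)^dcq(r),
                    numeric(1L)))^(1 / length(refs))
  eff_of(gene)^dcq(gene) / gm
}

# exhaustive fixed-reallocation p by relabelling whole samples
enum_realloc_p <- function(tab, gene) {
  samples <- unique(tab$sample_id)
  grp <- vapply(samples, function(s) unique(tab$group[tab$sample_id == s]),
                character(1L))
  n_case <- sum(grp == "case")
  obs <- abs(log(naive_pfaffl(tab, gene)))
  combos <- utils::combn(samples, n_case, simplify = FALSE)
  stats <- vapply(combos, function(cs) {
    t2 <- tab
    t2$group <- ifelse(t2$sample_id %in% cs, "case", "control")
    abs(log(naive_pfaffl(t2, gene)))
  }, numeric(1L))
  mean(stats >= obs - 1e-9)
}

# hand product-limit estimator (deaths before censorings at tied times)
km_hand <- function(time, event) {
  s <- 1
  out_t <- numeric()
  out_s <- numeric()
  for (tj in sort(unique(time))) {
    n_risk <- sum(time >= tj)
    d <- sum(time == tj & event == 1)
    s <- s * (1 - d / n_risk)
    out_t <- c(out_t, tj)
    out_s <- c(out_s, s)
  }
  list(time = out_t, surv = out_s)
}

# naive at-risk-weighted log-rank components for two groups
gbw_stat_hand <- function(time1, event1, time2, event2) {
  time <- c(time1, time2)
  event <- c(event1, event2)
  g <- rep(c(1, 2), c(length(time1), length(time2)))
  u <- 0
  v <- 0
  for (tj in sort(unique(time[event == 1]))) {
    nj <- sum(time >= tj)
    n1 <- sum(time >= tj & g == 1)
    dj <- sum(time == tj & event == 1)
    d1 <- sum(time == tj & event == 1 & g == 1)
    u <- u + nj * (d1 - dj * n1 / nj)
    if (nj > 1)
      v <- v + nj^2 * (n1 / nj) * (1 - n1 / nj) * dj * (nj - dj) / (nj - 1)
  }
  if (v > 0) u^2 / v else 0
}

# exact permutation p of the weighted statistic over all group assignments;
# also reports the largest atom of the discrete permutation distribution,
# which bounds how closely any continuous reference can match it
gbw_perm_p <- function(time, event, n1) {
  idx <- utils::combn(length(time), n1, simplify = FALSE)
  stat_of <- function(g1)
    gbw_stat_hand(time[g1], event[g1], time[-g1], event[-g1])
  obs <- stat_of(seq_len(n1))
  stats <- vapply(idx, stat_of, numeric(1L))
  list(p = mean(stats >= obs - 1e-9),
       atom = max(table(round(stats, 9))) / length(stats))
}

# small Cq table builder: one row per (gene, sample), single efficiency
make_cq <- function(values_by_gene, case_samples, ctrl_samples,
                    refs = "REF", efficiency = 2) {
  samples <- c(case_samples, ctrl_samples)
  rows <- do.call(rbind, lapply(names(values_by_gene), function(g) {
    data.frame(gene_id = g, sample_id = samples, replicate = 1L,
               cq = values_by_gene[[g]],
               efficiency = if (length(efficiency) > 1) efficiency[[g]]
                            else efficiency,
               is_reference = g %in% refs,
               group = rep(c("case", "control"),
                           c(length(case_samples), length(ctrl_samples))),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}
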