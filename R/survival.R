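#' Stratify patients by module-gene expression
#'
#' Patients are scored on a gene module and split into expression groups,
#' mirroring the "low / intermediate / high" sorting used for the survival
#' comparison. Two modes:
#' \describe{
#'   \item{`"cluster"` (default)}{each gene is z-scored across patients,
#'     patients are clustered hierarchically (squared-Euclidean distance
#'     between patient z-vectors, average linkage) and the tree is cut at
#'     `k`; clusters are then ranked by their mean module z-score.
#'     Euclidean (not correlation) distance is used here deliberately: a
#'     co-expressed module shifts a patient's whole z-vector up or down by
#'     a near-constant amount, which correlation distance is blind to.}
#'   \item{`"tertile"`}{patients are ranked by mean module z-score and cut
#'     into `k` equal-frequency groups.}
#' }
#' Group labels, lowest mean score first: `low`/`high` for k = 2,
#' `low`/`intermediate`/`high` for k = 3, `G1..Gk` otherwise.
#'
#' @param tab a survival table: data.frame with `patient_id` and one column
#'   per module gene (log2 expression).
#' @param genes module gene ids (columns of `tab`).
#' @param k number of groups (default 3), `k <=` number of patients.
#' @param mode `"cluster"` or `"tertile"`.
#' @return named character vector of class `stratification`
#'   (patient id -> group label), with `genes`, `k` and `mode` attributes.
#' @export
stratify <- function(tab, genes, k = 3L, mode = c("cluster", "tertile")) {
  mode <- match.arg(mode)
  missing <- setdiff(genes, names(tab))
  if (length(missing))
    stop("gene(s) not in table: ", paste(missing, collapse = ", "))
  n <- nrow(tab)
  if (k > n) stop("k exceeds the number of patients")
  x <- as.matrix(tab[, genes, drop = FALSE])
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant gene(s) across patients: ",
         paste(genes[sds == 0], collapse = ", "))
  z <- scale(x)
  rownames(z) <- tab$patient_id
  score <- rowMeans(z)
  cl <- if (mode == "cluster") {
    d <- distance_matrix(z, axis = "genes", method = "sqeuclidean")
    stats::cutree(cluster_tree(d), k = k)[tab$patient_id]
  } else {
    cut(rank(score, ties.method = "first"),
        breaks = stats::quantile(rank(score, ties.method = "first"),
                                 probs = seq(0, 1, length.out = k + 1L)),
        include.lowest = TRUE, labels = FALSE)
  }
  cl_means <- tapply(score, cl, mean)
  labels <- if (k == 2L) c("low", "high")
            else if (k == 3L) c("low", "intermediate", "high")
            else paste0("G", seq_len(k))
  label_of <- stats::setNames(labels, names(sort(cl_means)))
  out <- stats::setNames(unname(label_of[as.character(cl)]), tab$patient_id)
  attr(out, "genes") <- genes
  attr(out, "k") <- as.integer(k)
  attr(out, "mode") <- mode
  class(out) <- "stratification"
  out
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf("stratification: %d patients, k = %d (%s mode)\n",
              length(x), attr(x, "k"), attr(x, "mode")))
  print(table(unclass(x)))
  invisible(x)
}

#' Kaplan-Meier product-limit curve
#'
#' @param time follow-up times (days), > 0.
#' @param event 1 = death observed, 0 = censored.
#' @return an object of class `km_curve`: list with `time`, `surv`
#'   (non-increasing, starting below S(0) = 1), `n_risk`, `n_event`.
#' @export
km <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  med <- km_median(x)
  cat(sprintf("km_curve: n = %d, %d event time points, median = %s\n",
              x$n, length(x$time),
              if (is.na(med)) "not reached" else format(med)))
  invisible(x)
}

#' Median survival of a Kaplan-Meier curve
#'
#' The smallest event time at which the survival function drops to 0.5 or
#' below; `NA` when the curve never reaches 0.5 (median not attained).
#'
#' @param curve a `km_curve` from [km()].
#' @return days, or `NA`.
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  at_event <- curve$n_event > 0
  hit <- at_event & curve$surv <= 0.5 + 1e-12
  if (!any(hit)) return(NA_real_)
  min(curve$time[hit])
}

#' Gehan-Breslow-Wilcoxon test (at-risk-weighted log-rank)
#'
#' Weighted log-rank comparison of two survival samples with weight equal
#' to the total number at risk at each event time, which emphasizes early
#' deaths. At each distinct death time the observed-minus-expected deaths
#' in the first group is accumulated with hypergeometric variance, each
#' term weighted by the pooled risk-set size; the squared standardized sum
#' is referred to a chi-square distribution with 1 df (two-sided).
#'
#' @param a,b survival tables (data.frames) with columns `time_days` and
#'   `event`, both non-empty, with at least one death overall.
#' @return an object of class `htest` with `statistic` (chi-square) and
#'   `p.value`. Identical inputs give statistic 0 and p = 1; the test is
#'   symmetric in its arguments.
#' @export
gbw_test <- function(a, b) {
  for (tab in list(a, b)) {
    if (!is.data.frame(tab) || !all(c("time_days", "event") %in% names(tab)))
      stop("inputs must be data.frames with `time_days` and `event`")
    if (!nrow(tab)) stop("both groups must be non-empty")
  }
  time <- c(a$time_days, b$time_days)
  event <- c(a$event, b$event)
  grp <- rep(1:2, c(nrow(a), nrow(b)))
  if (!any(event == 1)) stop("no events in either group")
  death_times <- sort(unique(time[event == 1]))
  u <- 0; v <- 0
  for (tj in death_times) {
    at_risk <- time >= tj
    nj <- sum(at_risk)
    n1j <- sum(at_risk & grp == 1L)
    dj <- sum(time == tj & event == 1)
    d1j <- sum(time == tj & event == 1 & grp == 1L)
    u <- u + nj * (d1j - dj * n1j / nj)
    if (nj > 1L)
      v <- v + nj^2 * dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  stat <- if (v > 0) u^2 / v else 0
  structure(list(statistic = c(chisq = stat),
                 parameter = c(df = 1),
                 p.value = if (v > 0) stats::pchisq(stat, df = 1,
                                                    lower.tail = FALSE) else 1,
                 method = "Gehan-Breslow-Wilcoxon (at-risk-weighted log-rank)",
                 data.name = "two survival samples"),
            class = "htest")
}

#' Compare survival between two strata of a stratified table
#'
#' Convenience wrapper: subsets a survival table by a [stratify()] result,
#' fits [km()] per group and runs [gbw_test()] on the requested pair.
#'
#' @param tab survival table with `patient_id`, `time_days`, `event`.
#' @param strat a `stratification` over the same patients.
#' @param groups length-2 character vector of group labels to compare.
#' @return list with `curves` (named list of `km_curve`), `medians`
#'   (named vector) and `test` (the `htest`).
#' @export
survival_compare <- function(tab, strat, groups = c("high", "low")) {
  stopifnot(length(groups) == 2L)
  lab <- unclass(strat)[tab$patient_id]
  subs <- lapply(groups, function(g) tab[!is.na(lab) & lab == g, ,
                                         drop = FALSE])
  names(subs) <- groups
  empty <- !vapply(subs, nrow, integer(1L))
  if (any(empty))
    stop("empty stratum: ", paste(groups[empty], collapse = ", "))
  curves <- lapply(subs, function(s) km(s$time_days, s$event))
  list(curves = curves,
       medians = vapply(curves, km_median, numeric(1L)),
       test = gbw_test(subs[[1L]], subs[[2L]]))
}

#' Univariate logistic screen over probes
#'
#' Fits one logistic regression per probe with a dichotomous response
#' (e.g. high-grade vs low-grade tumor) and the probe's expression as the
#' sole covariate; reports the maximum-likelihood slope and its Wald
#' p-value. Complete separation is flagged and no p-value is reported for
#' that probe; a constant probe has, by convention, slope 0 and p = 1.
#'
#' @param y binary response (0/1 or logical), both classes present.
#' @param x numeric matrix, one column per probe (finite values).
#' @return data.frame with `probe`, `slope`, `p`, `separated`.
#' @export
logistic_screen <- function(y, x) {
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("probe values must be finite")
  if (nrow(x) != length(y)) stop("dimensions of y and x disagree")
  probes <- colnames(x)
  if (is.null(probes)) probes <- sprintf("probe%d", seq_len(ncol(x)))
  one <- function(j) {
    xv <- x[, j]
    if (stats::sd(xv) == 0)
      return(data.frame(probe = probes[j], slope = 0, p = 1,
                        separated = FALSE, stringsAsFactors = FALSE))
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ xv, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (!fit$converged) sep <- TRUE
    co <- summary(fit)$coefficients
    # complete separation can pass glm silently, leaving an absurd slope
    # with an enormous Wald SE (Hauck-Donner); treat that as separation
    if (abs(co["xv", "Estimate"]) > 15 || co["xv", "Std. Error"] > 100)
      sep <- TRUE
    data.frame(probe = probes[j], slope = unname(co["xv", "Estimate"]),
               p = if (sep) NA_real_ else unname(co["xv", "Pr(>|z|)"]),
               separated = sep, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(ncol(x)), one))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment with pass flags
#'
#' Step-up FDR adjustment of a p-value vector; a probe passes when its
#' adjusted value is at most `q`.
#'
#' @param p p-values (NA allowed; propagated).
#' @param q FDR level (default 0.10).
#' @return list with `adjusted` (monotone in the input order of p, bounded
#'   by 1) and `pass` (logical).
#' @export
bh_adjust <- function(p, q = 0.10) {
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, pass = !is.na(adjusted) & adjusted <= q)
}
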