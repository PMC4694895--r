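#' Population doubling time
#'
#' `PDT = t * log(2) / (log(Nt) - log(N0))` — the time for a culture growing
#' exponentially from `N0` to `Nt` cells over `t` days to double. The
#' logarithm base cancels; natural log is used. A shrinking culture
#' (`Nt < N0`) yields a negative PDT and a warning; `Nt == N0` is undefined
#' and errors. Vectorized; invariant to rescaling both counts.
#'
#' @param t elapsed time (days), > 0.
#' @param n0 initial cell count, > 0.
#' @param nt final cell count, > 0.
#' @return doubling time(s) in days.
#' @export
pdt <- function(t, n0, nt) {
  stopifnot(all(t > 0), all(n0 > 0), all(nt > 0))
  if (any(nt == n0))
    stop("PDT undefined when Nt equals N0")
  out <- t * log(2) / (log(nt) - log(n0))
  if (any(out < 0))
    warning("shrinking culture(s): negative PDT for ",
            sum(out < 0), " record(s)")
  out
}

#' Per-culture PDT from multi-passage growth records
#'
#' PDT is computed per passage and summarized per culture as mean and
#' (sample) SD, matching the usual "mean +/- SD per culture" presentation
#' of growth-parameter panels.
#'
#' @param records data.frame with columns `culture_id`, `t_days`, `n0`, `nt`.
#' @return data.frame with `culture_id`, `n_passages`, `pdt_mean`, `pdt_sd`.
#' @export
pdt_summary <- function(records) {
  need <- c("culture_id", "t_days", "n0", "nt")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("growth records lack column(s): ", paste(missing, collapse = ", "))
  vals <- pdt(records$t_days, records$n0, records$nt)
  out <- do.call(rbind, lapply(split(vals, records$culture_id), function(v)
    data.frame(n_passages = length(v), pdt_mean = mean(v),
               pdt_sd = if (length(v) > 1L) stats::sd(v) else 0)))
  data.frame(culture_id = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Sphere-assay summary
#'
#' Arithmetic means and population SDs of per-well sphere counts and
#' (optionally) per-sphere diameters for one culture.
#'
#' @param counts per-well sphere counts (>= 0), at least one well.
#' @param diameters optional per-sphere diameters (micrometres, > 0).
#' @return named vector with `mean_count`, `sd_count` and, when diameters
#'   are given, `mean_diameter`, `sd_diameter`.
#' @export
sphere_summary <- function(counts, diameters = NULL) {
  if (!length(counts)) stop("empty assay")
  stopifnot(all(counts >= 0))
  popsd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- c(mean_count = mean(counts), sd_count = popsd(counts))
  if (!is.null(diameters)) {
    stopifnot(all(diameters > 0))
    out <- c(out, mean_diameter = mean(diameters),
             sd_diameter = popsd(diameters))
  }
  out
}

#' Correlation between two per-culture assay read-outs
#'
#' Pearson correlation on cultures measured in both assays, matched by
#' name. Transforms (e.g. reciprocal PDT, so that faster growth is a larger
#' number) are applied by the caller.
#'
#' @param x,y named numeric vectors (culture -> value) with >= 3 cultures
#'   in common.
#' @return the coefficient.
#' @export
assay_correlation <- function(x, y) {
  shared <- intersect(names(x), names(y))
  if (length(shared) < 3L) stop("need at least 3 cultures in common")
  pearson_r(unname(x[shared]), unname(y[shared]))
}
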