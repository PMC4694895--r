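band_row <- function(protein, sample, band, band_bg = 100, control = 5100,
                     control_bg = 100) {
  data.frame(protein_id = protein, sample_id = sample, band = band,
             band_bg = band_bg, control = control, control_bg = control_bg,
             stringsAsFactors = FALSE)
}

test_that("RPE is background-subtracted, loading-control-normalized", {
  b <- rbind(band_row("P1", "s1", band = 5100),          # equals control
             band_row("P2", "s1", band = 500, band_bg = 100,
                      control = 300, control_bg = 100),  # net 400 / 200
             band_row("ACTB", "s1", band = 5100))        # control vs itself
  m <- rpe(b)
  expect_equal(unname(m["P1", "s1"]), 1)
  expect_equal(unname(m["P2", "s1"]), 2)
  expect_equal(unname(m["ACTB", "s1"]), 1)
})

test_that("below-background bands clamp to zero with a QC flag", {
  b <- rbind(band_row("GONE", "s1", band = 40, band_bg = 100),
             band_row("OK", "s1", band = 600))
  m <- rpe(b)
  expect_equal(unname(m["GONE", "s1"]), 0)
  qc <- attr(m, "qc_clamped")
  expect_identical(qc$protein_id, "GONE")
  bad <- band_row("P", "s9", band = 500, control = 90, control_bg = 100)
  expect_error(rpe(bad), "s9")
})

test_that("RNA-protein correlation matches over shared samples", {
  q <- c(s1 = 1, s2 = 2, s3 = 4, s4 = 8)
  expect_equal(rna_protein_r(q, q), 1)
  # sample matching is by name, not position
  expect_equal(rna_protein_r(q, rev(q)), 1)
  expect_error(rna_protein_r(q[1:2], q[1:2]), "3 shared")
  set.seed(14)
  a <- stats::setNames(rnorm(200), paste0("s", 1:200))
  b <- stats::setNames(rnorm(200), paste0("s", 1:200))
  expect_lt(abs(rna_protein_r(a, b)), 0.2)
  # common latent factor: r should recover the generative correlation
  f <- rnorm(100)
  r_true <- 1 / (1 + 0.5^2)   # x = f + e, var(e) = 0.25, per profile
  x <- stats::setNames(f + rnorm(100, sd = 0.5), paste0("s", 1:100))
  y <- stats::setNames(f + rnorm(100, sd = 0.5), paste0("s", 1:100))
  expect_lt(abs(rna_protein_r(x, y) - r_true), 0.1)
})

test_that("correlation summaries use the population-SD convention", {
  t1 <- load_table1()
  one <- summarize_correlations(t1, "CENPA")
  expect_equal(unname(one), c(0.76, 0))
  # signed aggregation flips exactly the three negative-correlation genes
  s_all <- summarize_correlations(t1, signed = TRUE)
  u_all <- summarize_correlations(t1, signed = FALSE)
  expect_lt(s_all[["mean"]], u_all[["mean"]])
  neg <- c("RAPGEF4", "RHBDD1", "MCC")
  s_neg <- summarize_correlations(t1, neg, signed = TRUE)
  expect_equal(s_neg[["mean"]],
               -summarize_correlations(t1, neg, signed = FALSE)[["mean"]])
  expect_error(summarize_correlations(t1, character()), "empty")
  expect_error(summarize_correlations(t1, "NOPE"), "NOPE")
})

test_that("sphere counts normalize to [0, 1] with the control at zero", {
  counts <- c(T65 = 62, T08 = 30, T96 = 8, NSC = 2)
  n <- normalize_sphere_counts(counts, baseline = 2)
  expect_equal(unname(n["T65"]), 1)
  expect_equal(unname(n["NSC"]), 0)
  expect_true(all(n >= 0 & n <= 1))
})

test_that("targeted-proteomics clustering handles appended features", {
  set.seed(26)
  samples <- paste0("s", 1:8)
  block1 <- matrix(rep(rnorm(8, 2), each = 3), 3, byrow = FALSE,
                   dimnames = list(c("PA", "PB", "PC"), samples))
  block2 <- matrix(rep(rnorm(8, 2), each = 3), 3, byrow = FALSE,
                   dimnames = list(c("PX", "PY", "PZ"), samples))
  m <- rbind(block1 + rnorm(24, sd = 0.05), block2 + rnorm(24, sd = 0.05))
  res <- targeted_proteomics_cluster(m)
  part <- cut_modules(res$tree, 2)
  expect_length(unique(unclass(part)[c("PA", "PB", "PC")]), 1L)
  expect_length(unique(unclass(part)[c("PX", "PY", "PZ")]), 1L)
  expect_length(unique(unclass(part)[c("PA", "PX")]), 2L)
  # a feature identical to a protein row sits at distance zero from it
  res2 <- targeted_proteomics_cluster(m, extra_features = list(
    spheres = m["PA", ]))
  expect_equal(res2$distance["spheres", "PA"], 0)
  expect_error(targeted_proteomics_cluster(m, extra_features = list(
    spheres = m["PA", 1:5])), "sample set")
})
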