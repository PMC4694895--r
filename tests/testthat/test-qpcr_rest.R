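test_that("the efficiency-corrected ratio reproduces analytic cases", {
  # identical Cq distributions in both groups -> ratio 1
  t0 <- make_cq(list(GX = c(20, 21, 20, 21), REF = c(18, 19, 18, 19)),
                c("c1", "c2"), c("n1", "n2"))
  expect_equal(pfaffl_ratio(t0, "GX"), 1)
  # E = 2, target dCq = 3, reference dCq = 0 -> 2^3
  t1 <- make_cq(list(GX = c(17, 17, 20, 20), REF = c(18, 18, 18, 18)),
                c("c1", "c2"), c("n1", "n2"))
  expect_equal(pfaffl_ratio(t1, "GX"), 8)
  # two references with dCq 1 and 3, target dCq 2: 2^2 / sqrt(2^1 * 2^3) = 1
  t2 <- make_cq(list(GX = c(18, 20), R1 = c(17, 18), R2 = c(15, 18)),
                "c1", "n1", refs = c("R1", "R2"))
  expect_equal(pfaffl_ratio(t2, "GX"), 2^2 / sqrt(2^1 * 2^3))
  expect_equal(pfaffl_ratio(t2, "GX"), 1)
  # agrees with the direct-formula oracle under heterogeneous efficiencies
  t3 <- make_cq(list(GX = c(17.2, 16.8, 20.4, 19.9),
                     R1 = c(18.1, 18.3, 18.0, 18.2),
                     R2 = c(16.0, 16.2, 16.1, 15.9)),
                c("c1", "c2"), c("n1", "n2"), refs = c("R1", "R2"),
                efficiency = list(GX = 1.9, R1 = 1.8, R2 = 2.0))
  expect_equal(pfaffl_ratio(t3, "GX"), naive_pfaffl(t3, "GX"))
})

test_that("replicates are averaged per sample before group means", {
  t1 <- make_cq(list(GX = c(17, 17, 20, 20), REF = c(18, 18, 18, 18)),
                c("c1", "c2"), c("n1", "n2"))
  reps <- t1[t1$sample_id == "c1" & t1$gene_id == "GX", ]
  reps$replicate <- 2L
  reps$cq <- 18                # replicates 16 and 18: sample mean still 17
  t1$cq[t1$sample_id == "c1" & t1$gene_id == "GX"] <- 16
  expect_equal(pfaffl_ratio(rbind(t1, reps), "GX"), 8)
})

test_that("sample-wise Cq shifts cancel through the references", {
  t1 <- make_cq(list(GX = c(17.5, 16.9, 20.1, 20.3),
                     REF = c(18.2, 17.9, 18.1, 18.0)),
                c("c1", "c2"), c("n1", "n2"))
  shifted <- t1
  shifted$cq[shifted$sample_id == "c2"] <-
    shifted$cq[shifted$sample_id == "c2"] + 1.7
  expect_equal(pfaffl_ratio(shifted, "GX"), pfaffl_ratio(t1, "GX"))
})

test_that("swapping group labels inverts the ratio and keeps p", {
  t1 <- make_cq(list(GX = c(17.5, 16.9, 20.1, 20.3, 19.8),
                     REF = c(18.2, 17.9, 18.1, 18.0, 18.1)),
                c("c1", "c2"), c("n1", "n2", "n3"))
  sw <- t1
  sw$group <- ifelse(t1$group == "case", "control", "case")
  expect_equal(pfaffl_ratio(sw, "GX"), 1 / pfaffl_ratio(t1, "GX"))
  expect_equal(reallocation_test(sw, "GX"), reallocation_test(t1, "GX"))
})

test_that("the reallocation test equals the enumeration oracle", {
  # canonical 2v2: values {1,2} vs {9,10}, constant reference -> p = 2/6
  t1 <- make_cq(list(GX = c(1, 2, 9, 10), REF = rep(5, 4)),
                c("c1", "c2"), c("n1", "n2"))
  expect_equal(reallocation_test(t1, "GX"), 2 / 6)
  expect_equal(reallocation_test(t1, "GX"), enum_realloc_p(t1, "GX"))
  # identical group values -> every reallocation ties the observed one
  t0 <- make_cq(list(GX = rep(7, 6), REF = rep(5, 6)),
                c("c1", "c2", "c3"), c("n1", "n2", "n3"))
  expect_equal(reallocation_test(t0, "GX"), 1)
  # random 3v3 and 4v4 toys against the oracle
  set.seed(19)
  for (n_per in c(3L, 4L)) {
    vals <- list(GX = rnorm(2 * n_per, 19, 1.2),
                 REF = rnorm(2 * n_per, 18, 0.3))
    tt <- make_cq(vals, paste0("c", seq_len(n_per)),
                  paste0("n", seq_len(n_per)))
    expect_equal(reallocation_test(tt, "GX"), enum_realloc_p(tt, "GX"))
  }
})

test_that("Monte-Carlo p agrees with the exhaustive p within 3 SE", {
  set.seed(33)
  vals <- list(GX = rnorm(8, 19, 1.5), REF = rnorm(8, 18, 0.3))
  tt <- make_cq(vals, paste0("c", 1:4), paste0("n", 1:4))
  p_ex <- reallocation_test(tt, "GX", iterations = 100)  # C(8,4)=70 <= 100
  p_mc <- reallocation_test(tt, "GX", iterations = 20000, seed = 7)
  se <- sqrt(p_ex * (1 - p_ex) / 20000)
  expect_lt(abs(p_mc - p_ex), 3 * se + 1e-4)
})

test_that("regulation calls follow the ratio/p contract", {
  expect_identical(call_regulation(8, 0.001), "UP")
  expect_identical(call_regulation(0.3, 0.2), "NS")
  expect_identical(call_regulation(0.3, 0.01), "DR")
  expect_identical(call_regulation(c(2, 0.5, 3), c(0.01, 0.01, 0.5)),
                   c("UP", "DR", "NS"))
  expect_error(call_regulation(-1, 0.5))
})

test_that("relative_expression recovers planted fold changes with calls", {
  cfg <- sim_config(seed = 6,
                    qpcr = qpcr_spec(fold_changes = c(UPG = 8, DNG = 0.25,
                                                      NUL = 1)))
  cq <- simulate_cq(cfg)
  res <- relative_expression(cq, seed = 41)
  expect_setequal(res$gene_id, c("UPG", "DNG", "NUL"))
  expect_identical(res$call[res$gene_id == "UPG"], "UP")
  expect_identical(res$call[res$gene_id == "DNG"], "DR")
  expect_identical(res$call[res$gene_id == "NUL"], "NS")
  expect_equal(res$ratio[res$gene_id == "UPG"], 8, tolerance = 0.15)
})

test_that("degenerate Cq tables are rejected", {
  t1 <- make_cq(list(GX = c(17, 20), REF = c(18, 18)), "c1", "n1")
  expect_error(reallocation_test(t1, "GX"), "at least 2")
  no_ref <- make_cq(list(GX = c(17, 17, 20, 20)), c("c1", "c2"),
                    c("n1", "n2"), refs = character())
  expect_error(pfaffl_ratio(no_ref, "GX"), "reference")
  one_group <- make_cq(list(GX = c(17, 17), REF = c(18, 18)),
                       c("c1", "c2"), character())
  expect_error(pfaffl_ratio(one_group, "GX"), "group")
})
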