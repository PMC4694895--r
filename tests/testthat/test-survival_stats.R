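surv_df <- function(time, event) data.frame(time_days = time, event = event)

test_that("stratification recovers well-separated planted levels", {
  set.seed(52)
  n_per <- 10L
  levels_ <- rep(c(-2, 0, 2), each = n_per)
  genes <- paste0("G", 1:5)
  tab <- data.frame(patient_id = sprintf("P%02d", seq_along(levels_)))
  for (g in genes) tab[[g]] <- levels_ + rnorm(length(levels_), sd = 0.1)
  strat <- stratify(tab, genes, k = 3)
  expect_identical(unname(as.vector(unclass(strat))),
                   rep(c("low", "intermediate", "high"), each = n_per))
  # the group with the largest mean z-score is labelled "high"
  z <- scale(as.matrix(tab[, genes]))
  means <- tapply(rowMeans(z), unclass(strat), mean)
  expect_identical(names(which.max(means)), "high")
  # tertile mode agrees on this clean separation
  strat_t <- stratify(tab, genes, k = 3, mode = "tertile")
  expect_identical(as.vector(unclass(strat_t)), as.vector(unclass(strat)))
})

test_that("stratification rejects degenerate input", {
  tab <- data.frame(patient_id = c("a", "b", "c"),
                    G1 = c(1, 1, 1), G2 = c(1, 2, 3))
  expect_error(stratify(tab, c("G1", "G2"), k = 2), "constant")
  expect_error(stratify(tab, "G9", k = 2), "not in table")
  expect_error(stratify(tab, "G2", k = 5), "exceeds")
})

test_that("KM curves match a hand product-limit computation", {
  set.seed(63)
  for (i in 1:5) {
    n <- sample(4:10, 1)
    time <- sample(1:12, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    curve <- km(time, event)
    hand <- km_hand(time, event)
    expect_equal(curve$time, hand$time)
    expect_equal(curve$surv, hand$surv)
    expect_true(all(diff(curve$surv) <= 1e-12))
    expect_true(all(curve$surv <= 1))
  }
})

test_that("KM medians follow the S(t) <= 0.5 convention", {
  expect_equal(km_median(km(1:5, rep(1, 5))), 3)
  expect_true(is.na(km_median(km(c(10, 20, 30), c(0, 0, 0)))))
  # censoring before the median pushes it later
  expect_equal(km_median(km(c(1, 2, 3, 4), c(1, 0, 1, 1))), 3)
})

test_that("the weighted log-rank test is null, symmetric and calibrated", {
  a <- surv_df(c(10, 20, 30, 40), c(1, 1, 0, 1))
  expect_equal(gbw_test(a, a)$statistic[["chisq"]], 0)
  expect_equal(gbw_test(a, a)$p.value, 1)
  b <- surv_df(c(5, 15, 18, 44), c(1, 0, 1, 1))
  expect_equal(gbw_test(a, b)$p.value, gbw_test(b, a)$p.value)
  expect_equal(gbw_test(a, b)$statistic, gbw_test(b, a)$statistic)
  expect_error(gbw_test(surv_df(numeric(), integer()), a), "non-empty")
  expect_error(gbw_test(surv_df(c(1, 2), c(0, 0)),
                        surv_df(c(3, 4), c(0, 0))), "no events")
  # statistic agrees with the naive hand computation
  expect_equal(gbw_test(a, b)$statistic[["chisq"]],
               gbw_stat_hand(a$time_days, a$event, b$time_days, b$event))
})

test_that("chi-square p tracks the exact permutation p on small fixtures", {
  set.seed(44)
  for (i in 1:10) {
    n1 <- sample(3:4, 1)
    n2 <- sample(3:4, 1)
    time <- round(rexp(n1 + n2, 1 / 100)) + 1
    event <- rbinom(n1 + n2, 1, 0.85)
    if (!any(event == 1)) next
    p_chi <- gbw_test(surv_df(time[1:n1], event[1:n1]),
                      surv_df(time[-(1:n1)], event[-(1:n1)]))$p.value
    perm <- gbw_perm_p(time, event, n1)
    # a continuous reference cannot agree more finely than the largest
    # atom of the discrete permutation distribution
    expect_lt(abs(p_chi - perm$p), 0.1 + perm$atom)
  }
})

test_that("the logistic screen matches the 2x2 closed form", {
  y <- c(rep(1, 30), rep(0, 30))
  x <- c(rep(1, 20), rep(0, 10), rep(1, 5), rep(0, 25))
  res <- logistic_screen(y, matrix(x, ncol = 1,
                                   dimnames = list(NULL, "probe1")))
  or_hand <- (20 / 10) / (5 / 25)
  expect_equal(res$slope, log(or_hand), tolerance = 1e-6)
  expect_false(res$separated)
  # constant predictor: slope 0, p = 1 by convention
  res0 <- logistic_screen(y, matrix(1, length(y), 1))
  expect_equal(res0$slope, 0)
  expect_equal(res0$p, 1)
  # complete separation is flagged, p withheld
  sep <- logistic_screen(y, matrix(as.numeric(y), ncol = 1))
  expect_true(sep$separated)
  expect_true(is.na(sep$p))
  expect_error(logistic_screen(rep(1, 10), matrix(rnorm(10))), "classes")
})

test_that("BH adjustment reproduces the step-up hand computation", {
  res <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), q = 0.10)
  expect_equal(res$adjusted, rep(0.04, 4))
  expect_true(all(res$pass))
  set.seed(70)
  p <- runif(50)
  adj <- bh_adjust(p)$adjusted
  expect_true(all(adj <= 1))
  expect_true(all(adj >= p - 1e-12))
  expect_equal(order(adj[order(p)]), seq_len(50))  # monotone in p-order
})

test_that("stratify-then-compare recovers the planted hazard difference", {
  cfg <- sim_config(seed = 88,
                    survival = survival_spec(n_patients = 300,
                                             hazard_multiplier = 2.5))
  tab <- simulate_survival(cfg)
  strat <- stratify(tab, survival_spec()$module_genes, k = 2)
  # planted groups recovered almost perfectly from expression
  expect_gt(mean(unclass(strat)[tab$patient_id] == tab$planted_group),
            0.97)
  cmp <- survival_compare(tab, strat, c("high", "low"))
  expect_lt(cmp$medians[["high"]], cmp$medians[["low"]])
  expect_lt(cmp$test$p.value, 0.05)
})
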