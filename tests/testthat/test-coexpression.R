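test_that("pearson_r behaves like the textbook coefficient", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, 2 * x + 7), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("distance_matrix matches a naive double loop to 1e-12", {
  set.seed(31)
  m <- matrix(rnorm(1000), 50, 20,
              dimnames = list(sprintf("G%02d", 1:50), NULL))
  d <- distance_matrix(m)
  expect_lt(max(abs(unclass(d) - naive_distance(m))), 1e-12)
  expect_true(isSymmetric(unclass(d)))
  expect_true(all(d >= 0 & d <= 2))
})

test_that("distance extremes: duplicates at 0, anti-correlation at 2", {
  m <- rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4), C = c(4, 3, 2, 1))
  d <- distance_matrix(m)
  expect_equal(d["A", "B"], 0)
  expect_equal(d["A", "C"], 2)
  expect_error(distance_matrix(rbind(A = c(1, 1, 1), B = 1:3)), "constant")
})

test_that("identical items merge first at height zero", {
  m <- rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4), C = c(9, 1, 4, 2))
  tree <- cluster_tree(distance_matrix(m))
  expect_equal(tree$height[1L], 0)
  first <- sort(tree$labels[-tree$merge[1L, ]])
  expect_identical(first, c("A", "B"))
  expect_identical(tree$method, "average")
})

test_that("planted modules are recovered exactly and order-invariantly", {
  mods <- list(list(id = "a", genes = sprintf("A%02d", 1:6), rho = 0.9),
               list(id = "b", genes = sprintf("B%02d", 1:6), rho = 0.9),
               list(id = "c", genes = sprintf("C%02d", 1:6), rho = 0.9))
  cfg <- sim_config(n_genes = 18, n_case = 20, n_control = 20,
                    planted_genes = character(), noise_sd = 1,
                    modules = mods, seed = 8)
  x <- simulate_expression(cfg)
  d <- distance_matrix(x)
  part <- cut_modules(cluster_tree(d), k = 3)
  for (m in mods)
    expect_length(unique(unclass(part)[m$genes]), 1L)
  expect_length(unique(unclass(part)[c("A01", "B01", "C01")]), 3L)
  # permuting the gene order leaves the partition unchanged
  set.seed(99)
  perm <- sample(rownames(x$values))
  d2 <- distance_matrix(x$values[perm, ])
  part2 <- cut_modules(cluster_tree(d2), k = 3)
  expect_identical(unclass(part)[names(part)],
                   unclass(part2)[names(part)])
  # within-module distances are smaller than between-module distances
  within <- unclass(d)[mods[[1]]$genes, mods[[1]]$genes]
  between <- unclass(d)[mods[[1]]$genes, mods[[2]]$genes]
  expect_lt(mean(within[upper.tri(within)]), mean(between))
})

test_that("tree cuts cover the degenerate k", {
  set.seed(4)
  m <- matrix(rnorm(40), 8, 5, dimnames = list(letters[1:8], NULL))
  tree <- cluster_tree(distance_matrix(m))
  expect_length(unique(unclass(cut_modules(tree, 1))), 1L)
  expect_length(unique(unclass(cut_modules(tree, 8))), 8L)
  expect_error(cut_modules(tree, 9), "out of range")
  expect_identical(sort(unique(unclass(cut_modules(tree, 3)))),
                   c("I", "II", "III"))
})

test_that("the PCA overview orders components and separates groups", {
  cfg <- sim_config(n_genes = 200, seed = 17, noise_sd = 0.5)
  x <- simulate_expression(cfg)
  p <- pca_overview(x, 2)
  v <- attr(p, "variance")
  expect_gte(v[1], v[2])
  # planted case/control shift is linearly separable on PC1
  pc1 <- split(p$PC1, p$group)
  expect_true(max(pc1$control) < min(pc1$case) ||
                min(pc1$control) > max(pc1$case))
  # duplicated sample lands on identical coordinates
  vals <- cbind(x$values, DUP = x$values[, 1L])
  meta <- rbind(x$metadata,
                data.frame(sample_id = "DUP", group = "case",
                           subtype = NA, culture_id = "DUP"))
  p2 <- pca_overview(expression_matrix(vals, meta), 2)
  expect_equal(p2[p2$sample_id == "DUP", c("PC1", "PC2")],
               p2[p2$sample_id == colnames(x$values)[1L], c("PC1", "PC2")],
               ignore_attr = TRUE)
  expect_error(pca_overview(x, 14), "fewer samples")
})
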