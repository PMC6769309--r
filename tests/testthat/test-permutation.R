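test_that("identical clouds give D = 0 and swapped groups negate D", {
  ds <- make_dataset(heterogeneity = 2, seed = 4, n_genes = 40, n_per_group = 8)
  halves <- split_by_group(ds$expression, ds$metadata)
  stat <- group_statistic("SDT0", "sample")
  expect_identical(group_statistic_difference(halves$case, halves$case, stat), 0)
  D <- group_statistic_difference(halves$case, halves$control, stat)
  expect_equal(group_statistic_difference(halves$control, halves$case, stat), -D)
  # Euler flavour too
  stat_e <- group_statistic("EULER", "sample", max_dim = 2)
  De <- group_statistic_difference(halves$case, halves$control, stat_e)
  expect_equal(group_statistic_difference(halves$control, halves$case, stat_e), -De)
})

test_that("heterogeneity inflates the case group's SDT0 almost surely", {
  hits <- vapply(1:30, function(s) {
    ds <- make_dataset(heterogeneity = 3, seed = 300 + s)
    halves <- split_by_group(ds$expression, ds$metadata)
    group_statistic_difference(halves$case, halves$control,
                               group_statistic("SDT0", "sample")) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("permutation nulls are seed-deterministic and fdr follows the rule", {
  ds <- make_dataset(heterogeneity = 1, seed = 17, n_genes = 30, n_per_group = 6)
  stat <- group_statistic("SDT0", "sample")
  a <- label_permutation_test(ds$expression, ds$metadata, stat, n_perm = 25, seed = 8)
  b <- label_permutation_test(ds$expression, ds$metadata, stat, n_perm = 25, seed = 8)
  expect_identical(a$null_values, b$null_values)
  expect_equal(a$fdr, mean(abs(a$null_values) >= abs(a$observed)))
  c2 <- label_permutation_test(ds$expression, ds$metadata, stat, n_perm = 25, seed = 9)
  expect_false(identical(a$null_values, c2$null_values))
  expect_error(label_permutation_test(ds$expression, ds$metadata, stat,
                                      n_perm = 0), class = "topohet_validation_error")
})

test_that("an observed D of zero is never significant (two-sided rule)", {
  set.seed(2)
  half <- matrix(rnorm(40 * 4, 8), 40, 4,
                 dimnames = list(sprintf("g%02d", 1:40), paste0("x", 1:4)))
  expr <- cbind(half, half)
  colnames(expr) <- paste0("s", 1:8)
  meta <- setNames(rep(c("A", "B"), each = 4), colnames(expr))
  res <- label_permutation_test(expr, meta, group_statistic("SDT0", "sample"),
                                n_perm = 19, seed = 1)
  expect_identical(res$observed, 0)
  expect_identical(res$fdr, 1)
})

test_that("gene-level statistics run through the lazy-witness path", {
  ds <- make_dataset(heterogeneity = 1, seed = 31, n_genes = 40, n_per_group = 10)
  stat <- group_statistic("SDT0", "gene", landmark_size = 10)
  halves <- split_by_group(ds$expression, ds$metadata)
  D1 <- group_statistic_difference(halves$case, halves$control, stat, seed = 5)
  D2 <- group_statistic_difference(halves$case, halves$control, stat, seed = 5)
  expect_identical(D1, D2)
  res <- label_permutation_test(ds$expression, ds$metadata, stat,
                                n_perm = 5, seed = 3)
  expect_length(res$null_values, 5L)
  expect_true(is.finite(res$observed))
})

test_that("gene-set filtering keeps sets with at least half their genes expressed", {
  expr <- matrix(rnorm(20), 10, 2,
                 dimnames = list(sprintf("g%02d", 1:10), c("s1", "s2")))
  sets <- list(half = c(sprintf("g%02d", 1:5), paste0("x", 1:5)),
               under = c(sprintf("g%02d", 1:4), paste0("x", 1:6)),
               full = sprintf("g%02d", 1:3))
  kept <- filter_genesets(sets, expr)
  expect_named(kept, c("half", "full"))
  expect_identical(kept$half, sprintf("g%02d", 1:5))   # intersected
  expect_identical(filter_genesets(list(), expr), list())
})

test_that("gene-set scan skips tiny sets, validates n_random, and is calibrated on decoys", {
  ds <- make_dataset(heterogeneity = 1, seed = 40, n_genes = 60, n_per_group = 8)
  sets <- list(tiny = rownames(ds$expression)[1:2],
               ok = rownames(ds$expression)[1:10])
  expect_error(geneset_topology_scan(ds$expression, ds$metadata, sets,
                                     n_random = 0), class = "topohet_validation_error")
  expect_warning(
    scan <- geneset_topology_scan(ds$expression, ds$metadata, sets,
                                  group_statistic("SDT0", "sample"),
                                  n_random = 9, seed = 2),
    "tiny")
  expect_identical(scan$per_set$set, "ok")

  # decoy calibration: on exchangeable data the fdr of a random set is uniform
  fdrs <- vapply(1:50, function(s) {
    ds <- make_dataset(heterogeneity = 1, seed = 400 + s, n_genes = 60,
                       n_per_group = 8)
    decoy <- list(decoy = rownames(ds$expression)[11:30])
    geneset_topology_scan(ds$expression, ds$metadata, decoy,
                          group_statistic("SDT0", "sample"),
                          n_random = 19, seed = s)$per_set$fdr
  }, numeric(1))
  expect_gt(mean(fdrs), 0.35)
  expect_lt(mean(fdrs), 0.65)
})

test_that("the affected gene set is flagged under restricted heterogeneity", {
  hits <- vapply(1:50, function(s) {
    ds <- generate_dataset(synth_config(n_genes = 200, n_per_group = 15,
                                        heterogeneity = 3, restricted = TRUE,
                                        affected_fraction = 0.1, seed = 500 + s))
    sets <- list(affected = ds$affected_genes)
    geneset_topology_scan(ds$expression, ds$metadata, sets,
                          group_statistic("SDT0", "sample"),
                          n_random = 99, seed = s)$per_set$fdr <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
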