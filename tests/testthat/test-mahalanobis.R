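test_that("closed-form models match hand calculations", {
  # 1 gene, controls {0, 2}: mean 1, sample variance 2, pinv 0.5
  controls <- matrix(c(0, 2), 1, 2, dimnames = list("g1", c("c1", "c2")))
  m <- fit_control_model(controls)
  expect_equal(unname(m$control_mean), 1)
  expect_equal(unname(m$cov_pinv), matrix(0.5))

  # identical controls: zero covariance, zero pseudoinverse, all MD = 0
  same <- matrix(c(1, 2, 1, 2), 2, 2,
                 dimnames = list(c("g1", "g2"), c("c1", "c2")))
  m0 <- suppressMessages(fit_control_model(same))
  expect_true(all(m0$cov_pinv == 0))
  expect_equal(mahalanobis_distance(m0, c(5, -3)), 0)

  # rank-1: controls (0,0), (1,1), (2,2) -> pinv all 0.25, MD((3,3)) = 2
  r1 <- matrix(c(0, 0, 1, 1, 2, 2), 2, 3,
               dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  mr <- suppressMessages(fit_control_model(r1))
  expect_equal(unname(mr$cov_pinv), matrix(0.25, 2, 2), tolerance = 1e-12)
  expect_equal(mahalanobis_distance(mr, c(3, 3)), 2, tolerance = 1e-12)

  expect_error(fit_control_model(r1[, 1, drop = FALSE]),
               class = "topohet_rank_error")
  expect_error(mahalanobis_distance(mr, c(1, 2, 3)),
               class = "topohet_alignment_error")
})

test_that("identity covariance reduces MD to the Euclidean norm", {
  set.seed(3)
  # controls engineered so cov is (nearly) identity: large sample of N(0, 1)
  controls <- matrix(rnorm(2 * 4000), 2, 4000,
                     dimnames = list(c("g1", "g2"), paste0("c", 1:4000)))
  m <- fit_control_model(controls)
  md <- mahalanobis_distance(m, m$control_mean + c(3, 4))
  expect_equal(md, 5, tolerance = 0.15)
  expect_equal(mahalanobis_distance(m, m$control_mean), 0)
})

test_that("full-rank MD agrees with the textbook inverse to 1e-10", {
  set.seed(9)
  for (trial in 1:10) {
    p <- sample(2:5, 1)
    controls <- matrix(rnorm(p * 30, 8), p, 30,
                       dimnames = list(paste0("g", 1:p), paste0("c", 1:30)))
    m <- fit_control_model(controls)
    S <- cov(t(controls))
    x <- rnorm(p, 8)
    direct <- sqrt(drop(t(x - m$control_mean) %*% solve(S) %*% (x - m$control_mean)))
    expect_equal(mahalanobis_distance(m, x), direct, tolerance = 1e-10)
    # and against pracma's pinv (the conventional implementation)
    expect_equal(m$cov_pinv, pracma::pinv(S), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("full-rank MD is invariant to invertible affine recoordinatization", {
  set.seed(14)
  p <- 3
  controls <- matrix(rnorm(p * 40), p, 40,
                     dimnames = list(paste0("g", 1:p), paste0("c", 1:40)))
  x <- rnorm(p)
  A <- matrix(rnorm(p * p), p, p) + diag(p) * 2
  b <- rnorm(p)
  tc <- A %*% controls + b
  dimnames(tc) <- dimnames(controls)
  md1 <- mahalanobis_distance(fit_control_model(controls), x)
  md2 <- mahalanobis_distance(fit_control_model(tc), drop(A %*% x + b))
  expect_equal(md1, md2, tolerance = 1e-8)
})

test_that("SSMD test is deterministic, additive, and powered at heterogeneity 3", {
  ds <- make_dataset(heterogeneity = 3, seed = 6)
  a <- ssmd_permutation_test(ds$expression, ds$metadata, n_perm = 20, seed = 3,
                             case_group = "case")
  b <- ssmd_permutation_test(ds$expression, ds$metadata, n_perm = 20, seed = 3,
                             case_group = "case")
  expect_identical(a$null_values, b$null_values)
  expect_equal(a$ssmd_observed, sum(a$per_sample_md^2), tolerance = 1e-12)
  expect_error(ssmd_permutation_test(ds$expression, ds$metadata, n_perm = 0),
               class = "topohet_validation_error")

  hits <- vapply(1:50, function(s) {
    ds <- make_dataset(heterogeneity = 3, seed = 600 + s)
    ssmd_permutation_test(ds$expression, ds$metadata, n_perm = 99, seed = s,
                          case_group = "case")$fdr <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("SSMD is calibrated under exchangeability", {
  fdrs <- vapply(1:30, function(s) {
    ds <- make_dataset(heterogeneity = 1, seed = 700 + s, n_genes = 40,
                       n_per_group = 10)
    ssmd_permutation_test(ds$expression, ds$metadata, n_perm = 49, seed = s,
                          case_group = "case")$fdr
  }, numeric(1))
  expect_gt(mean(fdrs), 0.3)
  expect_lt(mean(fdrs), 0.7)
})

test_that("SSMD gene-set scan flags affected sets and stays calibrated on decoys", {
  expect_error(
    ssmd_geneset_test(make_dataset(seed = 1)$expression,
                      make_dataset(seed = 1)$metadata, list(a = "g0001"),
                      n_random = 0),
    class = "topohet_validation_error")

  ds <- make_dataset(heterogeneity = 1, seed = 77, n_genes = 50, n_per_group = 8)
  expect_warning(
    scan <- ssmd_geneset_test(ds$expression, ds$metadata,
                              list(tiny = rownames(ds$expression)[1],
                                   ok = rownames(ds$expression)[1:8]),
                              n_random = 9, seed = 1, case_group = "case"),
    "tiny")
  expect_identical(scan$per_set$set, "ok")

  hits <- vapply(1:50, function(s) {
    ds <- generate_dataset(synth_config(n_genes = 200, n_per_group = 15,
                                        heterogeneity = 3, restricted = TRUE,
                                        affected_fraction = 0.1, seed = 800 + s))
    ssmd_geneset_test(ds$expression, ds$metadata,
                      list(affected = ds$affected_genes),
                      n_random = 99, seed = s,
                      case_group = "case")$per_set$fdr <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  decoy_fdrs <- vapply(1:50, function(s) {
    ds <- make_dataset(heterogeneity = 1, seed = 900 + s, n_genes = 60,
                       n_per_group = 8)
    ssmd_geneset_test(ds$expression, ds$metadata,
                      list(decoy = rownames(ds$expression)[11:30]),
                      n_random = 19, seed = s,
                      case_group = "case")$per_set$fdr
  }, numeric(1))
  expect_gt(mean(decoy_fdrs), 0.35)
  expect_lt(mean(decoy_fdrs), 0.65)
})
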