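test_that("tiny clouds produce the hand-computed diagrams", {
  # two points merging at their distance
  d2 <- matrix(c(0, 5, 5, 0), 2)
  dg <- as.data.frame(rips_persistence(d2, max_dim = 1))
  expect_identical(dg,
                   data.frame(dimension = c(0L, 0L), birth = c(0, 0),
                              death = c(5, Inf)))
  # a single point
  d1 <- matrix(0, 1, 1)
  expect_identical(as.data.frame(rips_persistence(d1, 1)),
                   data.frame(dimension = 0L, birth = 0, death = Inf))
  # square: adjacent 1, diagonal 1.5 -> one loop born 1, filled at 1.5
  sq <- matrix(1.5, 4, 4)
  for (p in list(c(1, 2), c(2, 3), c(3, 4), c(1, 4))) {
    sq[p[1], p[2]] <- sq[p[2], p[1]] <- 1
  }
  diag(sq) <- 0
  dg <- as.data.frame(rips_persistence(sq, max_dim = 1))
  expect_identical(dg,
                   data.frame(dimension = c(0L, 0L, 0L, 0L, 1L),
                              birth = c(0, 0, 0, 0, 1),
                              death = c(1, 1, 1, Inf, 1.5)))
})

test_that("rips matches the brute-force Z/2 elimination oracle on random clouds", {
  set.seed(101)
  for (trial in 1:60) {
    n <- sample(4:7, 1)
    d <- random_dissim(n)
    expect_same_diagram(rips_persistence(d, max_dim = 2), oracle_rips(d, 2))
  }
})

test_that("union-find dim-0 path equals rips and the MST oracle", {
  z <- as.matrix(dist(c(0, 1, 3)))
  expect_identical(as.data.frame(zero_dim_persistence(z)),
                   data.frame(dimension = c(0L, 0L, 0L), birth = c(0, 0, 0),
                              death = c(1, 2, Inf)))
  # n identical points: all pairs die at 0 (dropped), one essential survives
  same <- matrix(0, 5, 5)
  dg <- zero_dim_persistence(same)
  expect_identical(as.data.frame(dg),
                   data.frame(dimension = 0L, birth = 0, death = Inf))
  expect_equal(sdt0(dg), 0)

  set.seed(33)
  for (trial in 1:25) {
    d <- random_dissim(sample(4:15, 1))
    fast <- zero_dim_persistence(d)
    full <- rips_persistence(d, max_dim = 1)
    expect_same_diagram(fast, full[full$dimension == 0L, ])
    expect_equal(sdt0(fast), oracle_mst_weight(d), tolerance = 1e-12)
  }
})

test_that("dim-0 death times are 1-Lipschitz under matrix perturbation", {
  set.seed(12)
  d <- random_dissim(12)
  base <- sort(zero_dim_persistence(d)$death)
  delta <- 0.01
  pert <- d + matrix(runif(144, -delta, delta), 12, 12)
  pert <- (pert + t(pert)) / 2
  pert[pert < 0] <- 0
  diag(pert) <- 0
  shifted <- sort(zero_dim_persistence(pert)$death)
  fin <- is.finite(base)
  expect_true(all(abs(base[fin] - shifted[fin]) <= delta + 1e-12))
})

test_that("landmark selection is deterministic and covers the point set", {
  d <- as.matrix(dist(0:9))
  dimnames(d) <- NULL
  all_pts <- select_landmarks(d, 10)
  expect_setequal(all_pts$indices, 1:10)
  r1 <- select_landmarks(d, 4, method = "random", seed = 99)
  r2 <- select_landmarks(d, 4, method = "random", seed = 99)
  expect_identical(r1, r2)
  expect_error(select_landmarks(d, 1), class = "topohet_validation_error")
  expect_error(select_landmarks(d, 11), class = "topohet_validation_error")
})

test_that("maxmin landmarks on the line have non-increasing coverage radii", {
  d <- as.matrix(dist(0:9))
  # min-distance of each newly added landmark to the previous ones
  radii <- vapply(3:10, function(k) {
    idx <- select_landmarks(d, k)$indices
    min(d[idx[k], idx[-k]])
  }, numeric(1))
  expect_true(all(diff(radii) <= 1e-12))
  # deterministic start: smallest row sum is the middle of the line
  expect_identical(select_landmarks(d, 2)$indices[1],
                   unname(which.min(rowSums(d))))
})

test_that("lazy witness degenerates to rips when all points are landmarks", {
  set.seed(55)
  for (trial in 1:30) {
    d <- random_dissim(sample(3:7, 1))
    lm <- select_landmarks(d, nrow(d), nu = 1)
    expect_same_diagram(lazy_witness_persistence(d, lm, max_dim = 2),
                        rips_persistence(d, max_dim = 2), tol = 0)
  }
})

test_that("lazy witness on the {3,4,5} triangle gives dim-0 deaths {3,4}", {
  tr <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3)
  dg <- lazy_witness_persistence(tr, select_landmarks(tr, 3), max_dim = 1)
  expect_equal(sort(dg$death[is.finite(dg$death)]), c(3, 4))
})

test_that("lazy witness dim-0 pair counting is conserved", {
  set.seed(77)
  for (trial in 1:10) {
    d <- random_dissim(25)
    lm <- select_landmarks(d, 8)
    dg <- lazy_witness_persistence(d, lm, max_dim = 1)
    d0 <- dg[dg$dimension == 0L, ]
    n_ess <- sum(!is.finite(d0$death))
    # finite deaths (including any zero-length drops) complete the landmarks
    expect_lte(sum(is.finite(d0$death)), length(lm$indices) - n_ess)
    expect_gte(n_ess, 1L)
  }
})

test_that("the simplex-count guard refuses oversized enumerations", {
  d <- random_dissim(40)
  err <- tryCatch(rips_persistence(d, max_dim = 3, max_simplices = 1e4),
                  error = identity)
  expect_s3_class(err, "topohet_capacity_error")
  expect_match(conditionMessage(err), "lazy_witness")
})

test_that("diagram TSV round-trips including essential markers", {
  d <- random_dissim(6)
  dg <- rips_persistence(d, max_dim = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diagram(dg, path)
  expect_match(readLines(path), "inf", all = FALSE)
  back <- read_diagram(path)
  expect_same_diagram(back, dg, tol = 0)
})
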