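# Independent oracles kept deliberately naive and separate from the package
# implementation: dense Z/2 Gaussian elimination for full persistence,
# vegan's spanning tree for MST weight, and exhaustive split enumeration for
# tiny permutation designs.

random_dissim <- function(n, lo = 0.05, hi = 2) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, lo, hi)
  d <- d + t(d)
  dimnames(d) <- list(paste0("p", seq_len(n)), paste0("p", seq_len(n)))
  d
}

# Brute-force Vietoris-Rips persistence: enumerate simplices, build the full
# dense boundary matrix over Z/2, eliminate columns left to right.
oracle_rips <- function(d, max_dim) {
  n <- nrow(d)
  top <- min(max_dim + 1L, n - 1L)
  simplices <- list()
  for (k in 0:top) {
    sets <- combn(n, k + 1L, simplify = FALSE)
    for (vs in sets) {
      e <- 0
      if (k > 0L) {
        for (a in 1:k) for (b in (a + 1L):(k + 1L)) e <- max(e, d[vs[a], vs[b]])
      }
      simplices[[length(simplices) + 1L]] <- list(vs = vs, dim = k, eps = e)
    }
  }
  eps <- vapply(simplices, `[[`, numeric(1), "eps")
  dim_ <- vapply(simplices, `[[`, integer(1), "dim")
  lexkey <- vapply(simplices, function(s) {
    paste(sprintf("%04d", c(s$vs, rep(0L, top + 1L - length(s$vs)))),
          collapse = "")
  }, character(1))
  ord <- order(eps, dim_, lexkey)
  simplices <- simplices[ord]
  eps <- eps[ord]
  dim_ <- dim_[ord]
  m <- length(simplices)
  key_of <- vapply(simplices, function(s) paste(s$vs, collapse = ","), character(1))
  index_of <- stats::setNames(seq_len(m), key_of)
  B <- matrix(FALSE, m, m)
  for (j in seq_len(m)) {
    s <- simplices[[j]]
    if (s$dim == 0L) next
    for (drop_ix in seq_along(s$vs)) {
      face <- s$vs[-drop_ix]
      B[index_of[[paste(face, collapse = ",")]], j] <- TRUE
    }
  }
  low_of <- integer(m)           # column -> its pivot row (0 = zero column)
  owner_of <- integer(m)         # pivot row -> owning column
  for (j in seq_len(m)) {
    repeat {
      rows <- which(B[, j])
      if (!length(rows)) { low_of[j] <- 0L; break }
      piv <- max(rows)
      if (owner_of[piv] == 0L) { owner_of[piv] <- j; low_of[j] <- piv; break }
      B[, j] <- xor(B[, j], B[, owner_of[piv]])
    }
  }
  destroyed <- which(low_of != 0L)
  pairs <- data.frame(dimension = dim_[low_of[destroyed]],
                      birth = eps[low_of[destroyed]],
                      death = eps[destroyed])
  essential <- setdiff(which(low_of == 0L), low_of[destroyed])
  ess <- data.frame(dimension = dim_[essential], birth = eps[essential],
                    death = Inf)
  out <- rbind(pairs[pairs$death > pairs$birth & pairs$dimension <= max_dim, ],
               ess[ess$dimension <= max_dim, ])
  out <- out[order(out$dimension, out$birth, out$death), ]
  rownames(out) <- NULL
  out
}

oracle_mst_weight <- function(d) {
  sum(vegan::spantree(stats::as.dist(d))$dist)
}

# Exhaustive 2+2 permutation reference: D over all 6 ways to pick which two
# samples form group 1.
oracle_2plus2_fdr <- function(expr, observed_first_two, stat) {
  splits <- combn(4L, 2L, simplify = FALSE)
  Ds <- vapply(splits, function(g1) {
    g2 <- setdiff(1:4, g1)
    group_statistic_difference(expr[, g1, drop = FALSE],
                               expr[, g2, drop = FALSE], stat)
  }, numeric(1))
  obs <- group_statistic_difference(expr[, observed_first_two, drop = FALSE],
                                    expr[, setdiff(1:4, observed_first_two),
                                         drop = FALSE], stat)
  mean(abs(Ds) >= abs(obs))
}

expect_same_diagram <- function(a, b, tol = 1e-12) {
  da <- as.data.frame(a)[, c("dimension", "birth", "death")]
  db <- as.data.frame(b)[, c("dimension", "birth", "death")]
  da <- da[order(da$dimension, da$birth, da$death), ]
  db <- db[order(db$dimension, db$birth, db$death), ]
  rownames(da) <- rownames(db) <- NULL
  expect_equal(da, db, tolerance = tol)
}

# Small exchangeable / heterogeneous dataset factory used across tests.
make_dataset <- function(heterogeneity = 1, seed = 1, n_genes = 60,
                         n_per_group = 15, ...) {
  generate_dataset(synth_config(n_genes = n_genes, n_per_group = n_per_group,
                                heterogeneity = heterogeneity, seed = seed,
                                ...))
}
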