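#' @name persistence
#' @title Persistence diagrams with Z/2 coefficients
#' @description
#' [rips_persistence()] enumerates the full Vietoris-Rips flag filtration of a
#' dissimilarity matrix (a set of vertices spans a simplex once all its
#' pairwise dissimilarities are below the scale `eps`), orders simplices by
#' `(eps, dimension, lexicographic vertex tuple)` and runs the standard
#' boundary-matrix column reduction over Z/2. [zero_dim_persistence()] is an
#' exact dimension-0 fast path via Kruskal union-find: the finite death times
#' are precisely the minimum-spanning-tree edge weights.
#' [lazy_witness_persistence()] approximates the Rips filtration on a landmark
#' subset for large clouds.
#'
#' The filtration is truncated at `eps_max`, the maximum pairwise
#' dissimilarity; classes still alive there are *essential* (death `Inf` in
#' the diagram, the literal text `"inf"` on disk). Zero-length pairs
#' (`death == birth`) are dropped: they contribute nothing to any invariant.
NULL

# --- flag filtration construction -------------------------------------------

# Enumerate all simplices of the flag (clique) filtration of `d` up to
# dimension max_dim + 1. Returns parallel vectors eps, dim and a padded
# vertex matrix, already sorted by (eps, dim, lexicographic vertices),
# plus the boundary columns in that order.
build_flag_filtration <- function(d, max_dim, max_simplices = 1e7) {
  n <- nrow(d)
  top <- min(max_dim + 1L, n - 1L)
  total <- sum(choose(n, seq_len(top + 1L)))
  if (total > max_simplices) {
    stop_topohet(paste0(
      "flag filtration on %d points up to dimension %d has %.3g simplices ",
      "(ceiling %.3g); use lazy_witness_persistence() on a landmark subset"),
      n, top, total, max_simplices, class = "topohet_capacity_error")
  }
  verts <- vector("list", top + 1L)
  eps <- vector("list", top + 1L)
  verts[[1L]] <- matrix(seq_len(n), ncol = 1L)
  eps[[1L]] <- rep(0, n)
  for (k in seq_len(top)) {
    vm <- t(combn(n, k + 1L))
    e <- rep(0, nrow(vm))
    for (a in seq_len(k)) {
      for (b in seq(a + 1L, k + 1L)) {
        e <- pmax(e, d[cbind(vm[, a], vm[, b])])
      }
    }
    verts[[k + 1L]] <- vm
    eps[[k + 1L]] <- e
  }
  dims <- rep(0:top, times = vapply(verts, nrow, integer(1L)))
  epsv <- unlist(eps, use.names = FALSE)
  m <- length(epsv)
  pad <- matrix(0L, nrow = m, ncol = top + 1L)
  off <- 0L
  for (k in 0:top) {
    vm <- verts[[k + 1L]]
    pad[off + seq_len(nrow(vm)), seq_len(k + 1L)] <- vm
    off <- off + nrow(vm)
  }
  ord <- do.call(order, c(list(epsv, dims), lapply(seq_len(top + 1L),
                                                  function(j) pad[, j])))
  pos <- integer(m)
  pos[ord] <- seq_len(m)

  keys <- apply(pad, 1L, paste, collapse = ",")
  # boundary columns (positions of faces), in filtration order
  columns <- vector("list", m)
  for (j in seq_len(m)) {
    i <- ord[j]
    k <- dims[i]
    if (k == 0L) {
      columns[[j]] <- integer(0)
    } else {
      vs <- pad[i, seq_len(k + 1L)]
      fk <- vapply(seq_len(k + 1L), function(drop_ix) {
        paste(c(vs[-drop_ix], rep(0L, top + 1L - k)), collapse = ",")
      }, character(1L))
      columns[[j]] <- sort(pos[match(fk, keys)])
    }
  }
  list(eps = epsv[ord], dim = dims[ord], columns = columns, n = n)
}

assemble_diagram <- function(filt, max_dim, eps_max) {
  low <- reduce_boundary(filt$columns)
  m <- length(low)
  destroyed <- low != 0L
  creators_zero <- which(!destroyed)             # zero columns = class creators
  paired_creator <- low[destroyed]
  pairs <- data.frame(dimension = filt$dim[paired_creator],
                      birth = filt$eps[paired_creator],
                      death = filt$eps[destroyed])
  essential_ix <- setdiff(creators_zero, paired_creator)
  ess <- data.frame(dimension = filt$dim[essential_ix],
                    birth = filt$eps[essential_ix],
                    death = rep(Inf, length(essential_ix)))
  # dimension-0 conservation: finite + essential components == points
  n0 <- sum(pairs$dimension == 0L) + sum(ess$dimension == 0L)
  stopifnot(n0 == filt$n)
  diag_df <- rbind(pairs[pairs$death > pairs$birth & pairs$dimension <= max_dim, ],
                   ess[ess$dimension <= max_dim, ])
  new_diagram(diag_df, max_dim = max_dim, eps_max = eps_max, n_points = filt$n)
}

new_diagram <- function(df, max_dim, eps_max, n_points) {
  df <- df[order(df$dimension, df$birth, df$death), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("persistence_diagram", "data.frame"),
            max_dim = max_dim, eps_max = eps_max, n_points = n_points)
}

# --- public operations ------------------------------------------------------

#' Vietoris-Rips persistence diagram
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal (e.g. from
#'   [pearson_dissimilarity()]).
#' @param max_dim Highest homology dimension to report (0-3). Simplices up to
#'   `max_dim + 1` are enumerated.
#' @param max_simplices Guard on the total simplex count; beyond it the
#'   function refuses and points to [lazy_witness_persistence()].
#' @return A `persistence_diagram`: data frame with columns `dimension`,
#'   `birth`, `death` (`Inf` = essential class alive at `eps_max`), plus
#'   attributes `eps_max`, `max_dim`, `n_points`.
#' @export
rips_persistence <- function(d, max_dim = 2L, max_simplices = 1e7) {
  check_dissimilarity(d)
  if (max_dim < 0L || max_dim > 3L) {
    stop_topohet("max_dim must be between 0 and 3", class = "topohet_validation_error")
  }
  if (nrow(d) == 1L) {
    return(new_diagram(data.frame(dimension = 0L, birth = 0, death = Inf),
                       max_dim = max_dim, eps_max = 0, n_points = 1L))
  }
  filt <- build_flag_filtration(unname(d), as.integer(max_dim), max_simplices)
  assemble_diagram(filt, as.integer(max_dim), eps_max = max(d))
}

#' Exact dimension-0 persistence via union-find
#'
#' Kruskal's algorithm over edges sorted by weight: each union of two
#' components at weight `w` emits the finite pair `(0, w)`; the last surviving
#' component is essential. The multiset of finite death times equals the
#' minimum-spanning-tree edge weights, so `SDT0` equals the total MST weight.
#' Identical to the dimension-0 rows of [rips_persistence()] on the same
#' input, at a cost of `O(n^2 log n)`.
#'
#' @inheritParams rips_persistence
#' @return A `persistence_diagram` containing only dimension-0 pairs.
#' @export
zero_dim_persistence <- function(d) {
  check_dissimilarity(d)
  n <- nrow(d)
  if (n == 1L) {
    return(new_diagram(data.frame(dimension = 0L, birth = 0, death = Inf),
                       max_dim = 0L, eps_max = 0, n_points = 1L))
  }
  ij <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[ij]
  ord <- order(w, ij[, 1L], ij[, 2L])
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  deaths <- numeric(n - 1L)
  k <- 0L
  for (e in ord) {
    ra <- find(ij[e, 1L]); rb <- find(ij[e, 2L])
    if (ra != rb) {
      parent[ra] <- rb
      k <- k + 1L
      deaths[k] <- w[e]
      if (k == n - 1L) break
    }
  }
  df <- data.frame(dimension = 0L, birth = 0, death = deaths[seq_len(k)])
  df <- df[df$death > 0, , drop = FALSE]
  df <- rbind(df, data.frame(dimension = 0L, birth = 0, death = Inf))
  new_diagram(df, max_dim = 0L, eps_max = max(d), n_points = n)
}

#' Select landmark points for the lazy-witness filtration
#'
#' `"maxmin"` starts from the point with the smallest dissimilarity row sum
#' (lowest index among ties) and greedily adds the point maximizing its
#' minimum dissimilarity to the chosen landmarks (ties to the lowest index);
#' `"random"` samples uniformly without replacement under `seed`.
#'
#' @param d Dissimilarity matrix.
#' @param k Number of landmarks (`2 <= k <=` number of points).
#' @param method `"maxmin"` (deterministic, default) or `"random"`.
#' @param seed Seed for `method = "random"`.
#' @param nu Witness relaxation order carried to
#'   [lazy_witness_persistence()]: a witness's slack is its dissimilarity to
#'   its `nu`-th nearest landmark (`nu = 1` makes landmark witnesses exact).
#' @return An object of class `landmark_set` with fields `indices`, `method`,
#'   `seed`, `nu`.
#' @export
select_landmarks <- function(d, k, method = c("maxmin", "random"),
                             seed = 1L, nu = 1L) {
  method <- match.arg(method)
  check_dissimilarity(d)
  n <- nrow(d)
  if (k < 2L || k > n) {
    stop_topohet("landmark count k = %d out of range [2, %d]", k, n,
                 class = "topohet_validation_error")
  }
  if (nu < 1L) {
    stop_topohet("nu must be >= 1", class = "topohet_validation_error")
  }
  if (method == "maxmin") {
    idx <- integer(k)
    idx[1L] <- which.min(rowSums(d))     # lowest index among ties
    mind <- d[, idx[1L]]
    for (i in seq_len(k - 1L)) {
      mind[idx[seq_len(i)]] <- -Inf
      idx[i + 1L] <- which.max(mind)     # which.max takes the lowest index on ties
      mind <- pmin(mind, d[, idx[i + 1L]])
    }
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    idx <- sample.int(n, k)
  }
  structure(list(indices = as.integer(idx), method = method,
                 seed = as.integer(seed), nu = as.integer(nu)),
            class = "landmark_set")
}

# Entry times of landmark-landmark edges under the lazy-witness rule.
# Edge {a, b} enters at the smallest t >= 0 such that some witness w has
# max(d(a, w), d(b, w)) <= t + m(w), where m(w) is w's dissimilarity to its
# nu-th nearest landmark. Witnesses for an edge are the non-landmark points
# plus the edge's own endpoints; with landmarks = all points and nu = 1 every
# edge is witnessed only by its endpoints at exactly d(a, b), so the
# construction degenerates to the Vietoris-Rips filtration.
lw_edge_times <- function(d, landmarks) {
  idx <- landmarks$indices
  nu <- landmarks$nu
  n <- nrow(d)
  k <- length(idx)
  dl <- d[, idx, drop = FALSE]                 # point x landmark
  m_w <- apply(dl, 1L, function(row) sort(row)[nu])
  outside <- setdiff(seq_len(n), idx)
  t_mat <- matrix(0, k, k)
  for (a in seq_len(k - 1L)) {
    for (b in seq((a + 1L), k)) {
      wit <- c(outside, idx[a], idx[b])
      val <- pmax(dl[wit, a], dl[wit, b]) - m_w[wit]
      t_mat[a, b] <- t_mat[b, a] <- max(0, min(val))
    }
  }
  labs <- rownames(d)[idx] %||% as.character(idx)
  dimnames(t_mat) <- list(labs, labs)
  t_mat
}

#' Lazy-witness persistence diagram
#'
#' Sparse approximation of [rips_persistence()] for large point clouds: the
#' vertex set is a landmark subset, an edge between two landmarks enters the
#' filtration once some witness point is simultaneously within scale of both
#' endpoints (relaxed by the witness's dissimilarity to its `nu`-th nearest
#' landmark), and higher simplices fill in as soon as all their edges are
#' present (lazy/flag rule). Reduction and truncation are identical to the
#' full Rips path. With landmarks = all points and `nu = 1` the output equals
#' [rips_persistence()] exactly.
#'
#' @inheritParams rips_persistence
#' @param landmarks A [select_landmarks()] result.
#' @return A `persistence_diagram` over the landmark vertices.
#' @export
lazy_witness_persistence <- function(d, landmarks, max_dim = 3L,
                                     max_simplices = 1e7) {
  check_dissimilarity(d)
  stopifnot(inherits(landmarks, "landmark_set"))
  if (any(landmarks$indices < 1L | landmarks$indices > nrow(d)) ||
      anyDuplicated(landmarks$indices)) {
    stop_topohet("landmark indices invalid for a %d-point matrix", nrow(d),
                 class = "topohet_validation_error")
  }
  t_mat <- lw_edge_times(d, landmarks)
  rips_persistence(t_mat, max_dim = max_dim, max_simplices = max_simplices)
}

#' @export
as.data.frame.persistence_diagram <- function(x, ...) {
  data.frame(dimension = x$dimension, birth = x$birth, death = x$death)
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("persistence diagram: %d points, eps_max = %.4g\n",
              attr(x, "n_points"), attr(x, "eps_max")))
  tab <- table(factor(x$dimension, levels = 0:attr(x, "max_dim")),
               ifelse(is.finite(x$death), "finite", "essential"))
  print(tab)
  invisible(x)
}

#' Write / read a persistence diagram as TSV
#'
#' Columns `dimension`, `birth`, `death`; essential classes are encoded as the
#' literal text `inf`.
#'
#' @param diagram A `persistence_diagram`.
#' @param path File path.
#' @return `path` (write) or the reloaded `persistence_diagram` (read).
#' @export
write_diagram <- function(diagram, path) {
  df <- as.data.frame(diagram)
  df$death <- ifelse(is.finite(df$death), sprintf("%.17g", df$death), "inf")
  df$birth <- sprintf("%.17g", df$birth)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$death <- ifelse(df$death == "inf", Inf, suppressWarnings(as.numeric(df$death)))
  new_diagram(df[, c("dimension", "birth", "death")],
              max_dim = max(df$dimension),
              eps_max = max(df$death[is.finite(df$death)], df$birth, 0),
              n_points = NA_integer_)
}
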