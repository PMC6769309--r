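#' Specify a group-difference topological statistic
#'
#' @param kind `"SDT0"` (sum of death times of connected components) or
#'   `"EULER"` (Euler characteristic `chi`).
#' @param level `"sample"` — each group's samples form the point cloud (full
#'   Vietoris-Rips, or the exact union-find path for `SDT0`); `"gene"` — each
#'   group's genes form the cloud, analysed by lazy-witness persistence over
#'   that group's own landmark selection.
#' @param max_dim Homology dimension cap; defaults to 2 at sample level and 3
#'   at gene level (gene clouds show occasional three-dimensional cycles).
#' @param landmark_size,landmark_method,nu Landmark parameters (gene level
#'   only; default 20 maxmin landmarks, `nu = 1`).
#' @return An object of class `group_statistic`.
#' @export
group_statistic <- function(kind = c("SDT0", "EULER"),
                            level = c("sample", "gene"),
                            max_dim = NULL, landmark_size = 20L,
                            landmark_method = c("maxmin", "random"),
                            nu = 1L) {
  kind <- match.arg(kind)
  level <- match.arg(level)
  landmark_method <- match.arg(landmark_method)
  if (is.null(max_dim)) max_dim <- if (level == "sample") 2L else 3L
  structure(list(kind = kind, level = level, max_dim = as.integer(max_dim),
                 landmark_size = as.integer(landmark_size),
                 landmark_method = landmark_method, nu = as.integer(nu)),
            class = "group_statistic")
}

# Invariant of one group's point cloud under a group_statistic spec.
group_invariant <- function(expr, stat, seed = 1L) {
  if (stat$level == "sample") {
    d <- pearson_dissimilarity(expr, "samples")
    if (stat$kind == "SDT0") {
      sdt0(zero_dim_persistence(d))
    } else {
      euler_characteristic(rips_persistence(d, max_dim = stat$max_dim))
    }
  } else {
    d <- pearson_dissimilarity(expr, "genes")
    lm <- select_landmarks(d, min(stat$landmark_size, nrow(d)),
                           method = stat$landmark_method, seed = seed,
                           nu = stat$nu)
    if (stat$kind == "SDT0") {
      # dimension 0 of the lazy-witness flag complex is exact union-find on
      # the witness edge-entry times
      sdt0(zero_dim_persistence(lw_edge_times(d, lm)))
    } else {
      euler_characteristic(
        lazy_witness_persistence(d, lm, max_dim = stat$max_dim))
    }
  }
}

#' Difference of a topological invariant between two groups
#'
#' Computes the level-appropriate dissimilarity matrix, persistence and
#' invariant for each group independently and returns
#' `invariant(exprA) - invariant(exprB)`. In a labelled analysis, group A is
#' the first group label in sort order (so `case - control` for labels
#' `"case"`/`"control"`).
#'
#' @param exprA,exprB Expression matrices with identical gene rows and equal
#'   sample counts.
#' @param stat A [group_statistic()].
#' @param seed Seed driving landmark selection at gene level (per-group
#'   sub-seeds are derived from it).
#' @return A single number `D`.
#' @export
group_statistic_difference <- function(exprA, exprB, stat = group_statistic(),
                                       seed = 1L) {
  stopifnot(inherits(stat, "group_statistic"))
  if (!identical(rownames(exprA), rownames(exprB))) {
    stop_topohet("the two groups must share an identical gene universe",
                 class = "topohet_contract_error")
  }
  if (ncol(exprA) != ncol(exprB)) {
    stop_topohet("groups must have equal sample counts (%d vs %d)",
                 ncol(exprA), ncol(exprB), class = "topohet_contract_error")
  }
  group_invariant(exprA, stat, seed = derive_seed(seed, "landmarks", 1L)) -
    group_invariant(exprB, stat, seed = derive_seed(seed, "landmarks", 2L))
}

# "More extreme" rule shared by all permutation/resampling tests.
# two-sided: |null| >= |observed| (conservative, symmetric); greater: null >=
# observed. The reported quantity follows the source analysis's terminology
# ("permutation FDR") although operationally it is an empirical permutation
# p-value.
extremeness_fraction <- function(null_values, observed,
                                 sided = c("two", "greater")) {
  sided <- match.arg(sided)
  if (sided == "two") mean(abs(null_values) >= abs(observed))
  else mean(null_values >= observed)
}

#' Label-permutation test of a topological group difference
#'
#' The observed statistic is `D = invariant(group 1) - invariant(group 2)`
#' (group labels in sort order). Each permutation re-partitions the pooled
#' samples uniformly at random into two equal halves (group sizes preserved),
#' recomputes both dissimilarity matrices, persistence and `D` from scratch,
#' and the permutation FDR is the proportion of null values more extreme than
#' the observed one.
#'
#' @param expr Expression matrix.
#' @param meta Named group assignment (two equal-sized groups covering
#'   `colnames(expr)`).
#' @param stat A [group_statistic()].
#' @param n_perm Number of permutations (`>= 1`).
#' @param seed Master seed; each permutation (including any gene-level
#'   landmark re-selection) draws its own derived sub-seed.
#' @param sided `"two"` (default: `|null| >= |observed|`) or `"greater"`.
#' @return An object of class `permutation_test`: `observed`, `null_values`,
#'   `fdr`, `n_perm`, `seed`, `sided`, `statistic`.
#' @export
label_permutation_test <- function(expr, meta, stat = group_statistic(),
                                   n_perm = 1000L, seed = 1L,
                                   sided = c("two", "greater")) {
  sided <- match.arg(sided)
  if (n_perm < 1L) {
    stop_topohet("n_perm must be >= 1", class = "topohet_validation_error")
  }
  meta <- match_groups(expr, meta)
  groups <- split_by_group(expr, meta)
  observed <- group_statistic_difference(groups[[1L]], groups[[2L]], stat,
                                         seed = derive_seed(seed, "observed"))
  n <- ncol(expr)
  half <- n %/% 2L
  null_values <- vapply(seq_len(n_perm), function(i) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(derive_seed(seed, "perm", i))
    idx <- sample.int(n)
    group_statistic_difference(expr[, idx[seq_len(half)], drop = FALSE],
                               expr[, idx[seq(half + 1L, n)], drop = FALSE],
                               stat, seed = derive_seed(seed, "permstat", i))
  }, numeric(1L))
  structure(list(observed = observed, null_values = null_values,
                 fdr = extremeness_fraction(null_values, observed, sided),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 sided = sided, statistic = stat,
                 groups = names(groups)),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("label-permutation test of D_%s (%s level, %s-sided)\n",
              if (x$statistic$kind == "SDT0") "SDT" else "chi",
              x$statistic$level, x$sided))
  cat(sprintf("  D = %s - %s = %.6g\n", x$groups[1L], x$groups[2L], x$observed))
  cat(sprintf("  permutation FDR (as defined in the source analysis) = %.4g  [%d permutations, seed %d]\n",
              x$fdr, x$n_perm, x$seed))
  invisible(x)
}

#' Filter gene sets by expression coverage
#'
#' Keeps the sets with at least `min_fraction` (default one half) of their
#' member genes present among the matrix's genes, and intersects the retained
#' sets with that expressed universe.
#'
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param expr Expression matrix defining the expressed universe.
#' @param min_fraction Minimum fraction of member genes that must be present.
#' @return The filtered, intersected collection (possibly empty), with the
#'   `descriptions` attribute subset accordingly.
#' @export
filter_genesets <- function(sets, expr, min_fraction = 0.5) {
  universe <- rownames(expr)
  keep <- vapply(sets, function(g) mean(g %in% universe) >= min_fraction,
                 logical(1L))
  out <- lapply(sets[keep], function(g) intersect(g, universe))
  descs <- attr(sets, "descriptions")
  if (!is.null(descs)) attr(out, "descriptions") <- descs[names(out)]
  out
}

#' Gene-set topology scan against size-matched random sets
#'
#' For each gene set, computes the observed group difference `D` on the
#' expression matrix restricted to the set's genes (sample-level clouds), then
#' compares it with `D` values from `n_random` random gene sets of the same
#' size drawn uniformly without replacement from the expressed universe. Sets
#' smaller than 3 genes after intersection are skipped with a warning
#' (correlation needs at least 3 coordinates to be non-degenerate).
#'
#' @inheritParams label_permutation_test
#' @param sets Gene-set collection, ideally pre-filtered with
#'   [filter_genesets()] (re-intersected here defensively).
#' @param n_random Number of random sets per gene set (`>= 1`).
#' @return An object of class `geneset_scan`: data frame `per_set` with
#'   columns `set`, `size_used`, `observed_D`, `fdr`, plus `null_D` (list of
#'   null vectors), `n_random`, `seed`.
#' @export
geneset_topology_scan <- function(expr, meta, sets, stat = group_statistic(),
                                  n_random = 100L, seed = 1L,
                                  sided = c("two", "greater")) {
  sided <- match.arg(sided)
  if (n_random < 1L) {
    stop_topohet("n_random must be >= 1", class = "topohet_validation_error")
  }
  if (stat$level != "sample") {
    stop_topohet("gene-set scans use sample-level statistics",
                 class = "topohet_validation_error")
  }
  meta <- match_groups(expr, meta)
  universe <- rownames(expr)
  scan_stat <- function(genes, sub_seed) {
    groups <- split_by_group(expr[genes, , drop = FALSE], meta)
    group_statistic_difference(groups[[1L]], groups[[2L]], stat, seed = sub_seed)
  }
  rows <- list()
  nulls <- list()
  for (nm in names(sets)) {
    genes <- intersect(sets[[nm]], universe)
    if (length(genes) < 3L) {
      warning(sprintf("gene set '%s' has %d expressed gene(s) (< 3); skipped",
                      nm, length(genes)), call. = FALSE)
      next
    }
    observed <- scan_stat(genes, derive_seed(seed, paste0("obs:", nm)))
    null_D <- vapply(seq_len(n_random), function(r) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(derive_seed(seed, paste0("set:", nm), r))
      scan_stat(sample(universe, length(genes)),
                derive_seed(seed, paste0("setstat:", nm), r))
    }, numeric(1L))
    rows[[nm]] <- data.frame(set = nm, size_used = length(genes),
                             observed_D = observed,
                             fdr = extremeness_fraction(null_D, observed, sided))
    nulls[[nm]] <- null_D
  }
  per_set <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), size_used = integer(0),
               observed_D = numeric(0), fdr = numeric(0))
  rownames(per_set) <- NULL
  structure(list(per_set = per_set, null_D = nulls,
                 n_random = as.integer(n_random), seed = as.integer(seed),
                 sided = sided, statistic = stat),
            class = "geneset_scan")
}

#' @export
print.geneset_scan <- function(x, ...) {
  cat(sprintf("gene-set scan: %d set(s) tested against %d size-matched random sets each\n",
              nrow(x$per_set), x$n_random))
  print(x$per_set[order(x$per_set$fdr), ], row.names = FALSE)
  cat("apply your own multiple-testing correction across sets if required\n")
  invisible(x)
}

#' Export a gene-set scan as TSV
#'
#' One row per tested set: name, size used, observed statistic, permutation
#' FDR.
#'
#' @param scan A `geneset_scan` (or SSMD variant).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(scan$per_set, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
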