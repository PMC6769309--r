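#' Fit the control-group Mahalanobis model
#'
#' Estimates the per-gene mean and the sample covariance (denominator `n - 1`)
#' of the control samples, and its Moore-Penrose generalized inverse. In the
#' usual genes >> samples regime the covariance is singular by construction;
#' the pseudoinverse (singular values below `rank_tolerance` times the largest
#' treated as zero) handles this, and a message reports the covariance rank.
#'
#' @param controls Expression matrix of the control samples (genes x samples,
#'   `>= 2` columns).
#' @param rank_tolerance Relative singular-value cutoff; default is the
#'   conventional `machine epsilon * max(dim)`.
#' @return An object of class `mahalanobis_model`: `control_mean`, `cov_pinv`,
#'   `rank`, `rank_tolerance`, `gene_ids`.
#' @export
fit_control_model <- function(controls, rank_tolerance = NULL) {
  check_expression(controls)
  if (ncol(controls) < 2L) {
    stop_topohet("need >= 2 control samples to estimate a covariance",
                 class = "topohet_rank_error")
  }
  p <- nrow(controls)
  control_mean <- rowMeans(controls)
  S <- cov(t(controls))
  if (is.null(rank_tolerance)) rank_tolerance <- .Machine$double.eps * max(dim(S))
  sv <- svd(S)
  cut <- rank_tolerance * max(sv$d, 0)
  pos <- sv$d > cut
  rank <- sum(pos)
  cov_pinv <- if (rank == 0L) {
    matrix(0, p, p)
  } else {
    sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  }
  cov_pinv <- (cov_pinv + t(cov_pinv)) / 2
  dimnames(cov_pinv) <- list(rownames(controls), rownames(controls))
  if (rank < p) {
    message(sprintf("control covariance is singular: rank %d of %d; using the pseudoinverse",
                    rank, p))
  }
  structure(list(control_mean = control_mean, cov_pinv = cov_pinv,
                 rank = rank, rank_tolerance = rank_tolerance,
                 gene_ids = rownames(controls)),
            class = "mahalanobis_model")
}

#' @export
print.mahalanobis_model <- function(x, ...) {
  cat(sprintf("Mahalanobis control model: %d genes, covariance rank %d\n",
              length(x$gene_ids), x$rank))
  invisible(x)
}

#' Mahalanobis distance of samples from the control centroid
#'
#' `MD(x) = sqrt((x - mean)' pinv(Sigma) (x - mean))`, with the quadratic form
#' clipped at zero before the square root to guard vanishing negative
#' floating-point artifacts.
#'
#' @param model A [fit_control_model()].
#' @param x Numeric vector aligned to `model$gene_ids`, or a genes x samples
#'   matrix.
#' @return Non-negative distance(s), named by sample for matrix input.
#' @export
mahalanobis_distance <- function(model, x) {
  stopifnot(inherits(model, "mahalanobis_model"))
  if (is.matrix(x)) {
    if (nrow(x) != length(model$gene_ids)) {
      stop_topohet("sample matrix has %d genes; model expects %d",
                   nrow(x), length(model$gene_ids),
                   class = "topohet_alignment_error")
    }
    diffs <- x - model$control_mean
    q <- colSums(diffs * (model$cov_pinv %*% diffs))
    return(sqrt(pmax(q, 0)))
  }
  if (length(x) != length(model$gene_ids)) {
    stop_topohet("sample vector has length %d; model expects %d",
                 length(x), length(model$gene_ids),
                 class = "topohet_alignment_error")
  }
  diff <- x - model$control_mean
  sqrt(max(0, sum(diff * (model$cov_pinv %*% diff))))
}

# SSMD of a case matrix under a control-fitted model.
ssmd_value <- function(model, cases) {
  sum(mahalanobis_distance(model, cases)^2)
}

resolve_case_group <- function(meta, case_group) {
  labels <- sort(unique(meta))
  if (is.null(case_group)) case_group <- labels[1L]
  if (!case_group %in% labels) {
    stop_topohet("case group '%s' not among labels: %s", case_group,
                 paste(labels, collapse = ", "),
                 class = "topohet_metadata_error")
  }
  case_group
}

#' SSMD label-permutation test
#'
#' The observed statistic is the sum of squared Mahalanobis distances (SSMD)
#' of the case samples from the control centroid under the control-fitted
#' model. Each permutation re-splits the pooled samples into two equal halves,
#' refits the model on the permuted controls (the only null-respecting choice)
#' and recomputes the SSMD of the permuted cases. Because SSMD is a
#' non-negative dispersion measure asking whether cases are more dispersed
#' than chance, extremeness is one-sided: `fdr = mean(null >= observed)`.
#'
#' @param expr Expression matrix.
#' @param meta Group assignment (two equal-sized groups).
#' @param n_perm Number of permutations (`>= 1`).
#' @param seed Master seed (per-permutation sub-seeds derived).
#' @param case_group Label of the case group; default: the first group label
#'   in sort order.
#' @param rank_tolerance Passed to [fit_control_model()].
#' @return An object of class `ssmd_test`: `ssmd_observed`, `per_sample_md`,
#'   `null_values`, `fdr`, `n_perm`, `seed`.
#' @export
ssmd_permutation_test <- function(expr, meta, n_perm = 1000L, seed = 1L,
                                  case_group = NULL, rank_tolerance = NULL) {
  if (n_perm < 1L) {
    stop_topohet("n_perm must be >= 1", class = "topohet_validation_error")
  }
  meta <- match_groups(expr, meta)
  case_group <- resolve_case_group(meta, case_group)
  cases <- expr[, names(meta)[meta == case_group], drop = FALSE]
  controls <- expr[, names(meta)[meta != case_group], drop = FALSE]
  model <- suppressMessages(fit_control_model(controls, rank_tolerance))
  md <- mahalanobis_distance(model, cases)
  observed <- sum(md^2)
  n <- ncol(expr)
  half <- n %/% 2L
  null_values <- vapply(seq_len(n_perm), function(i) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(derive_seed(seed, "ssmd_perm", i))
    idx <- sample.int(n)
    perm_cases <- expr[, idx[seq_len(half)], drop = FALSE]
    perm_controls <- expr[, idx[seq(half + 1L, n)], drop = FALSE]
    m <- suppressMessages(fit_control_model(perm_controls, rank_tolerance))
    ssmd_value(m, perm_cases)
  }, numeric(1L))
  structure(list(ssmd_observed = observed, per_sample_md = md,
                 null_values = null_values,
                 fdr = mean(null_values >= observed),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 case_group = case_group, model_rank = model$rank),
            class = "ssmd_test")
}

#' @export
print.ssmd_test <- function(x, ...) {
  cat(sprintf("SSMD label-permutation test (case group '%s')\n", x$case_group))
  cat(sprintf("  observed SSMD = %.6g over %d case samples (covariance rank %d)\n",
              x$ssmd_observed, length(x$per_sample_md), x$model_rank))
  cat(sprintf("  permutation FDR (as defined in the source analysis) = %.4g  [%d permutations, seed %d]\n",
              x$fdr, x$n_perm, x$seed))
  invisible(x)
}

#' SSMD gene-set scan against size-matched random sets
#'
#' Per gene set: refits the control model on the set's genes, computes the
#' observed case SSMD, and compares it (one-sided, `null >= observed`) with
#' SSMD values over `n_random` random gene sets of the same size drawn from
#' the expressed universe. Sets with fewer than 2 expressed genes are skipped
#' with a warning.
#'
#' @inheritParams ssmd_permutation_test
#' @param sets Gene-set collection (pre-filter with [filter_genesets()]).
#' @param n_random Number of random sets per gene set (`>= 1`).
#' @return An object of class `ssmd_geneset_scan` with the same shape as
#'   [geneset_topology_scan()] (`observed_D` column holds the observed SSMD).
#' @export
ssmd_geneset_test <- function(expr, meta, sets, n_random = 100L, seed = 1L,
                              case_group = NULL, rank_tolerance = NULL) {
  if (n_random < 1L) {
    stop_topohet("n_random must be >= 1", class = "topohet_validation_error")
  }
  meta <- match_groups(expr, meta)
  case_group <- resolve_case_group(meta, case_group)
  case_ids <- names(meta)[meta == case_group]
  ctrl_ids <- names(meta)[meta != case_group]
  universe <- rownames(expr)
  set_ssmd <- function(genes) {
    m <- suppressMessages(
      fit_control_model(expr[genes, ctrl_ids, drop = FALSE], rank_tolerance))
    ssmd_value(m, expr[genes, case_ids, drop = FALSE])
  }
  rows <- list()
  nulls <- list()
  for (nm in names(sets)) {
    genes <- intersect(sets[[nm]], universe)
    if (length(genes) < 2L) {
      warning(sprintf("gene set '%s' has %d expressed gene(s) (< 2); skipped",
                      nm, length(genes)), call. = FALSE)
      next
    }
    observed <- set_ssmd(genes)
    null_vals <- vapply(seq_len(n_random), function(r) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(derive_seed(seed, paste0("ssmd_set:", nm), r))
      set_ssmd(sample(universe, length(genes)))
    }, numeric(1L))
    rows[[nm]] <- data.frame(set = nm, size_used = length(genes),
                             observed_D = observed,
                             fdr = mean(null_vals >= observed))
    nulls[[nm]] <- null_vals
  }
  per_set <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), size_used = integer(0),
               observed_D = numeric(0), fdr = numeric(0))
  rownames(per_set) <- NULL
  structure(list(per_set = per_set, null_D = nulls,
                 n_random = as.integer(n_random), seed = as.integer(seed),
                 case_group = case_group),
            class = c("ssmd_geneset_scan", "geneset_scan"))
}
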