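#' Configuration for the synthetic expression generator
#'
#' Defines a two-group log2-scale expression dataset with modular gene-gene
#' correlation and a tunable inter-sample heterogeneity multiplier applied to
#' the case group. With `heterogeneity = 1` the two groups follow the
#' identical generative law (exchangeable), so every downstream
#' group-difference statistic has a symmetric null.
#'
#' @param n_genes Number of genes (rows).
#' @param n_per_group Samples per group; the dataset has `2 * n_per_group`
#'   columns.
#' @param n_modules Number of co-expression modules; genes are assigned
#'   round-robin.
#' @param module_strength Latent-factor loading in `[0, 1)` shared by all
#'   genes of a module.
#' @param noise_sd Standard deviation of the per-gene residual noise
#'   (log2 units).
#' @param heterogeneity Within-group dispersion multiplier (`>= 1`) applied to
#'   the residual scale of the case group only; group means are untouched so
#'   differential-expression-style mean shifts never confound the topology.
#' @param affected_fraction Fraction of genes carrying the heterogeneity when
#'   `restricted = TRUE`; the affected count is `floor(affected_fraction *
#'   n_genes)`.
#' @param restricted If `TRUE`, only the affected gene subset of case samples
#'   has its residual scale inflated.
#' @param seed Master seed; the generator is fully deterministic given the
#'   config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 100L, n_per_group = 15L, n_modules = 5L,
                         module_strength = 0.7, noise_sd = 0.7,
                         heterogeneity = 1, affected_fraction = 0.1,
                         restricted = FALSE, seed = 1L) {
  chk <- function(ok, msg) if (!ok) stop_topohet(msg, class = "topohet_config_error")
  chk(is.numeric(n_genes) && n_genes >= 2, "n_genes must be >= 2")
  chk(is.numeric(n_per_group) && n_per_group >= 2, "n_per_group must be >= 2")
  chk(is.numeric(n_modules) && n_modules >= 1, "n_modules must be >= 1")
  chk(is.numeric(module_strength) && module_strength >= 0 && module_strength < 1,
      "module_strength must be in [0, 1)")
  chk(is.numeric(noise_sd) && noise_sd > 0, "noise_sd must be positive")
  chk(is.numeric(heterogeneity) && heterogeneity >= 1, "heterogeneity must be >= 1")
  chk(is.numeric(affected_fraction) && affected_fraction >= 0 && affected_fraction <= 1,
      "affected_fraction must be in [0, 1]")
  chk(is.logical(restricted) && length(restricted) == 1L, "restricted must be TRUE/FALSE")
  chk(is.numeric(seed) && is.finite(seed), "seed must be an integer")
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 n_modules = as.integer(n_modules),
                 module_strength = module_strength, noise_sd = noise_sd,
                 heterogeneity = heterogeneity,
                 affected_fraction = affected_fraction,
                 restricted = restricted, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic grouped expression dataset
#'
#' Generative model (fixed): gene `i` of module `m` in sample `s` has
#' `expr = baseline_i + module_strength * z[m, s] + sigma_{i,s} * e[i, s]`
#' with `baseline_i ~ N(8, 1)` (plausible log2 scale), module latent factors
#' `z ~ N(0, 1)` independent per sample, residuals `e ~ N(0, noise_sd)`, and
#' `sigma = 1` for control samples and `sigma = heterogeneity` for case
#' samples (all genes, or only the affected subset when `restricted`).
#' Separate deterministic sub-seeds drive gene baselines, factors, noise and
#' the affected-gene draw, so changing `n_per_group` never reshuffles gene
#' baselines.
#'
#' @param config A [synth_config()].
#' @return An object of class `synth_dataset`: list with `expression`
#'   (matrix), `metadata` (named character, labels `"case"`/`"control"`),
#'   `affected_genes` (character, possibly empty) and `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  p <- config$n_genes
  n <- config$n_per_group
  gene_ids <- sprintf("g%04d", seq_len(p))
  sample_ids <- c(sprintf("case_%02d", seq_len(n)),
                  sprintf("control_%02d", seq_len(n)))
  groups <- stats::setNames(rep(c("case", "control"), each = n), sample_ids)
  module_of <- rep_len(seq_len(config$n_modules), p)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  set.seed(derive_seed(config$seed, "genes"))
  baseline <- rnorm(p, mean = 8, sd = 1)

  affected <- character(0)
  if (config$restricted) {
    k <- floor(config$affected_fraction * p)
    if (k > 0) {
      set.seed(derive_seed(config$seed, "affected"))
      affected <- sort(sample(gene_ids, k))
    }
  }

  set.seed(derive_seed(config$seed, "factors"))
  z <- matrix(rnorm(config$n_modules * 2L * n), nrow = config$n_modules)

  set.seed(derive_seed(config$seed, "noise"))
  e <- matrix(rnorm(p * 2L * n, sd = config$noise_sd), nrow = p)

  sigma <- matrix(1, nrow = p, ncol = 2L * n)
  case_cols <- seq_len(n)
  if (config$heterogeneity > 1) {
    if (config$restricted) {
      sigma[gene_ids %in% affected, case_cols] <- config$heterogeneity
    } else {
      sigma[, case_cols] <- config$heterogeneity
    }
  }

  values <- baseline + config$module_strength * z[module_of, , drop = FALSE] +
    sigma * e
  dimnames(values) <- list(gene_ids, sample_ids)

  structure(list(expression = values, metadata = groups,
                 affected_genes = affected, config = config),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("synthetic expression dataset: %d genes x %d samples (%d per group)\n",
              cfg$n_genes, 2L * cfg$n_per_group, cfg$n_per_group))
  cat(sprintf("  heterogeneity %.2f (%s), %d modules, seed %d\n",
              cfg$heterogeneity,
              if (cfg$restricted) sprintf("restricted to %d genes", length(x$affected_genes))
              else "all genes",
              cfg$n_modules, cfg$seed))
  invisible(x)
}

#' Write a synthetic dataset as analysis-ready fixture files
#'
#' Emits `expression.tsv`, `metadata.csv` and, when the dataset has affected
#' genes, `genesets.gmt` holding the `affected` set plus size-matched decoy
#' sets drawn (deterministically, from the dataset seed) from the unaffected
#' genes. The files use exactly the formats [read_expression()],
#' [read_metadata()] and [read_gmt()] consume.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @param n_decoys Number of decoy sets in the GMT.
#' @return Named character vector of file paths written.
#' @export
write_dataset <- function(dataset, dir, n_decoys = 5L) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.csv"))
  write_expression(dataset$expression, paths[["expression"]])
  write.csv(data.frame(sample_id = names(dataset$metadata),
                       group = unname(dataset$metadata)),
            paths[["metadata"]], row.names = FALSE, quote = FALSE)
  if (length(dataset$affected_genes)) {
    k <- length(dataset$affected_genes)
    unaffected <- setdiff(rownames(dataset$expression), dataset$affected_genes)
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    sets <- list(affected = dataset$affected_genes)
    for (i in seq_len(n_decoys)) {
      set.seed(derive_seed(dataset$config$seed, "decoy", i))
      sets[[sprintf("decoy_%02d", i)]] <- sort(sample(unaffected, min(k, length(unaffected))))
    }
    attr(sets, "descriptions") <- stats::setNames(
      c("genes carrying extra heterogeneity",
        rep("size-matched unaffected decoy", n_decoys)), names(sets))
    paths[["genesets"]] <- file.path(dir, "genesets.gmt")
    write_gmt(sets, paths[["genesets"]])
  }
  paths
}
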