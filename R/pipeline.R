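#' Build a pipeline run configuration
#'
#' Defaults mirror the analysis conventions throughout the package: 20
#' landmarks at gene level, 100 random sets per gene-set scan, Euler
#' characteristic from dimensions 0-2.
#'
#' @param analysis One of `"simulate"`, `"sample-topology"`,
#'   `"gene-topology"`, `"geneset-topology"`, `"mahalanobis"`,
#'   `"geneset-mahalanobis"`.
#' @param expression_path,metadata_path,geneset_path Input files (TSV / CSV /
#'   GMT); `geneset_path` only for gene-set analyses.
#' @param statistic `"SDT0"` or `"EULER"` (topology analyses).
#' @param max_dim Homology dimension cap (`NULL` = level default).
#' @param landmark_size,nu Lazy-witness parameters (gene level).
#' @param n_perm,n_random_sets Resampling depths.
#' @param sided `"two"` or `"greater"` (topology tests; SSMD is always
#'   one-sided high).
#' @param drop_constant Drop constant genes before splitting groups.
#' @param case_group Case label for the Mahalanobis track (default: first
#'   label in sort order).
#' @param simulate Named list of [synth_config()] arguments (for
#'   `analysis = "simulate"`).
#' @param seed Master seed.
#' @param output_dir Directory for `report.json`, diagram TSVs and scan
#'   tables.
#' @return A `run_config` list.
#' @export
analysis_config <- function(analysis = c("sample-topology", "gene-topology",
                                         "geneset-topology", "mahalanobis",
                                         "geneset-mahalanobis", "simulate"),
                            expression_path = NULL, metadata_path = NULL,
                            geneset_path = NULL, statistic = "SDT0",
                            max_dim = NULL, landmark_size = 20L, nu = 1L,
                            n_perm = 1000L, n_random_sets = 100L,
                            sided = "two", drop_constant = FALSE,
                            case_group = NULL, simulate = list(),
                            seed = 1L, output_dir = ".") {
  analysis <- match.arg(analysis)
  structure(list(analysis = analysis, expression_path = expression_path,
                 metadata_path = metadata_path, geneset_path = geneset_path,
                 statistic = statistic, max_dim = max_dim,
                 landmark_size = as.integer(landmark_size), nu = as.integer(nu),
                 n_perm = as.integer(n_perm),
                 n_random_sets = as.integer(n_random_sets), sided = sided,
                 drop_constant = isTRUE(drop_constant),
                 case_group = case_group, simulate = simulate,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Fields are the arguments of [analysis_config()]; unknown fields are an
#' error.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_topohet("unknown config field(s): %s", paste(unknown, collapse = ", "),
                 class = "topohet_config_error")
  }
  do.call(analysis_config, vals)
}

run_stat <- function(config) {
  level <- if (config$analysis == "gene-topology") "gene" else "sample"
  group_statistic(kind = config$statistic, level = level,
                  max_dim = config$max_dim,
                  landmark_size = config$landmark_size, nu = config$nu)
}

#' Run an end-to-end analysis
#'
#' Dispatches on `config$analysis`, writes `report.json` (config echo, result,
#' per-group diagram summaries, package version, wall clock, seed) plus
#' per-group diagram TSVs and, for scans, a per-set TSV into
#' `config$output_dir`. Every reported number is reproducible from the input
#' files, the config and the seed alone. Partial outputs are removed if a
#' stage fails.
#'
#' @param config A [analysis_config()] or [read_config()] result.
#' @return The report, invisibly (class `run_report`).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  note <- function(p) written <<- c(written, p)
  on.exit({
    # failure path: remove partial outputs
    if (!isTRUE(attr(written, "complete"))) unlink(written)
  })
  log_msg <- function(fmt, ...) message(sprintf(paste0("[topohet] ", fmt), ...))

  report <- list(config = unclass(config),
                 version = as.character(packageVersion("topohet")),
                 seed = config$seed)

  if (config$analysis == "simulate") {
    ds <- generate_dataset(do.call(synth_config,
                                   c(config$simulate, list(seed = config$seed))))
    paths <- write_dataset(ds, out)
    for (p in paths) note(p)
    report$files <- as.list(paths)
    report$affected_genes <- ds$affected_genes
  } else {
    if (is.null(config$expression_path) || !file.exists(config$expression_path)) {
      stop_topohet("expression path missing or not found: %s",
                   config$expression_path %||% "<NULL>",
                   class = "topohet_io_error")
    }
    if (is.null(config$metadata_path) || !file.exists(config$metadata_path)) {
      stop_topohet("metadata path missing or not found: %s",
                   config$metadata_path %||% "<NULL>",
                   class = "topohet_io_error")
    }
    expr <- read_expression(config$expression_path)
    meta <- read_metadata(config$metadata_path)
    if (config$drop_constant) expr <- drop_constant_genes(expr)
    meta <- match_groups(expr, meta)
    log_msg("loaded %d genes x %d samples (%s)", nrow(expr), ncol(expr),
            paste(sort(unique(meta)), collapse = " vs "))

    needs_sets <- config$analysis %in% c("geneset-topology", "geneset-mahalanobis")
    sets <- NULL
    if (needs_sets) {
      if (is.null(config$geneset_path) || !file.exists(config$geneset_path)) {
        stop_topohet("gene-set path missing or not found: %s",
                     config$geneset_path %||% "<NULL>",
                     class = "topohet_io_error")
      }
      sets <- filter_genesets(read_gmt(config$geneset_path), expr)
      log_msg("%d gene set(s) pass the expression filter", length(sets))
    }

    if (config$analysis %in% c("sample-topology", "gene-topology")) {
      stat <- run_stat(config)
      groups <- split_by_group(expr, meta)
      dir.create(file.path(out, "diagrams"), showWarnings = FALSE)
      summaries <- list()
      for (g in names(groups)) {
        d <- pearson_dissimilarity(groups[[g]],
                                   if (stat$level == "sample") "samples" else "genes")
        diagram <- if (stat$level == "sample") {
          rips_persistence(d, max_dim = stat$max_dim)
        } else {
          lm <- select_landmarks(d, min(stat$landmark_size, nrow(d)),
                                 method = stat$landmark_method,
                                 seed = derive_seed(config$seed, "report_landmarks"),
                                 nu = stat$nu)
          lazy_witness_persistence(d, lm, max_dim = stat$max_dim)
        }
        p <- file.path(out, "diagrams", paste0(g, ".tsv"))
        write_diagram(diagram, p)
        note(p)
        s <- summarize_diagram(diagram)
        summaries[[g]] <- list(per_dim = s$per_dim, chi = s$chi)
      }
      report$group_summaries <- summaries
      res <- label_permutation_test(expr, meta, stat, n_perm = config$n_perm,
                                    seed = config$seed, sided = config$sided)
      report$result <- unclass(res)[c("observed", "fdr", "n_perm", "sided",
                                      "groups", "null_values")]
    } else if (config$analysis == "geneset-topology") {
      res <- geneset_topology_scan(expr, meta, sets, run_stat(config),
                                   n_random = config$n_random_sets,
                                   seed = config$seed, sided = config$sided)
      p <- file.path(out, "genesets.tsv")
      write_scan(res, p)
      note(p)
      report$result <- list(per_set = res$per_set, n_random = res$n_random)
    } else if (config$analysis == "mahalanobis") {
      res <- ssmd_permutation_test(expr, meta, n_perm = config$n_perm,
                                   seed = config$seed,
                                   case_group = config$case_group)
      report$result <- unclass(res)[c("ssmd_observed", "fdr", "n_perm",
                                      "case_group", "model_rank",
                                      "null_values")]
      report$result$per_sample_md <- as.list(res$per_sample_md)
    } else {
      res <- ssmd_geneset_test(expr, meta, sets,
                               n_random = config$n_random_sets,
                               seed = config$seed,
                               case_group = config$case_group)
      p <- file.path(out, "genesets.tsv")
      write_scan(res, p)
      note(p)
      report$result <- list(per_set = res$per_set, n_random = res$n_random)
    }
  }

  report$wall_clock_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  rp <- file.path(out, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  note(rp)
  attr(written, "complete") <- TRUE
  log_msg("done in %.2f s; report at %s", report$wall_clock_sec, rp)
  invisible(structure(report, class = "run_report"))
}

#' Plot a persistence diagram
#'
#' Scatter of (birth, death) per finite pair, one plotting symbol per
#' dimension, with the diagonal as reference; essential classes are drawn at
#' the top margin and annotated with the infinity symbol.
#'
#' @param diagram A `persistence_diagram`.
#' @param path Optional PNG path; when given the plot is written there,
#'   otherwise drawn on the current device.
#' @param main Plot title.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_diagram <- function(diagram, path = NULL, main = "persistence diagram") {
  stopifnot(inherits(diagram, "persistence_diagram"))
  if (!is.null(path)) {
    grDevices::png(path, width = 640, height = 640)
    on.exit(grDevices::dev.off())
  }
  eps_max <- attr(diagram, "eps_max") %||% 1
  if (!is.finite(eps_max) || eps_max <= 0) eps_max <- 1
  top <- eps_max * 1.08
  fin <- diagram[is.finite(diagram$death), , drop = FALSE]
  ess <- diagram[!is.finite(diagram$death), , drop = FALSE]
  dims <- sort(unique(c(0L, diagram$dimension)))
  pchs <- c(19, 17, 15, 18)[seq_along(dims)]
  plot(NA, xlim = c(0, top), ylim = c(0, top), xlab = "birth", ylab = "death",
       main = main, asp = 1)
  graphics::abline(0, 1, col = "grey60")
  for (i in seq_along(dims)) {
    rows <- fin[fin$dimension == dims[i], , drop = FALSE]
    if (nrow(rows)) graphics::points(rows$birth, rows$death, pch = pchs[i],
                                     col = i + 1L)
  }
  if (nrow(ess)) {
    graphics::points(ess$birth, rep(top, nrow(ess)),
                     pch = pchs[match(ess$dimension, dims)],
                     col = match(ess$dimension, dims) + 1L)
    graphics::text(ess$birth, rep(top, nrow(ess)), labels = "∞", pos = 4)
  }
  graphics::legend("bottomright", legend = paste("dim", dims),
                   pch = pchs, col = seq_along(dims) + 1L, bty = "n")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("topohet run report: %s (seed %d, %.2f s)\n",
              x$config$analysis, x$seed, x$wall_clock_sec))
  if (!is.null(x$result$fdr)) {
    cat(sprintf("  observed = %.6g, permutation FDR = %.4g\n",
                x$result$observed %||% x$result$ssmd_observed, x$result$fdr))
  }
  invisible(x)
}
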