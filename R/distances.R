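#' Correlation dissimilarity matrix over samples or genes
#'
#' Builds the point cloud of a group as a symmetric dissimilarity matrix with
#' entries `1 - r` (`r` = Pearson correlation), zero diagonal, over either the
#' samples (columns correlated across genes) or the genes (rows correlated
#' across samples). Values lie in `[0, 2]`: 0 for perfectly correlated, 2 for
#' perfectly anticorrelated vectors.
#'
#' @param expr Expression matrix (genes x samples).
#' @param axis `"samples"` for the inter-sample cloud, `"genes"` for the
#'   inter-gene cloud.
#' @return Symmetric numeric matrix with zero diagonal, labels as dimnames and
#'   attribute `metric_name = "one_minus_pearson"`.
#' @details Any constant vector (zero variance) is an error naming the
#'   offending gene or sample: its correlation is undefined and silent removal
#'   would desynchronize gene universes between groups. Use
#'   [drop_constant_genes()] before splitting if constant genes are expected.
#' @export
pearson_dissimilarity <- function(expr, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  check_expression(expr)
  if (axis == "genes" && ncol(expr) < 2L) {
    stop_topohet("gene-level correlation needs >= 2 samples",
                 class = "topohet_rank_error")
  }
  if (axis == "samples" && nrow(expr) < 2L) {
    stop_topohet("sample-level correlation needs >= 2 genes",
                 class = "topohet_rank_error")
  }
  m <- if (axis == "samples") expr else t(expr)
  # columns of m are the vectors being correlated
  sds <- apply(m, 2L, sd)
  if (any(sds == 0)) {
    offender <- colnames(m)[which(sds == 0)[1L]]
    stop_topohet("constant %s '%s' has undefined Pearson correlation",
                 if (axis == "samples") "sample" else "gene", offender,
                 class = "topohet_constant_error")
  }
  d <- 1 - cor(m)
  # clamp floating-point spill and force exact symmetry/zero diagonal
  d[d < 0] <- 0
  d[d > 2] <- 2
  d[upper.tri(d)] <- t(d)[upper.tri(d)]
  diag(d) <- 0
  attr(d, "metric_name") <- "one_minus_pearson"
  d
}

check_dissimilarity <- function(d) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d)) {
    stop_topohet("dissimilarity must be a square numeric matrix",
                 class = "topohet_type_error")
  }
  if (!all(is.finite(d))) {
    stop_topohet("dissimilarity matrix contains non-finite entries",
                 class = "topohet_validation_error")
  }
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0)) {
    stop_topohet("dissimilarity must be symmetric with zero diagonal",
                 class = "topohet_validation_error")
  }
  invisible(d)
}

#' Export a dissimilarity matrix as TSV (labels in header and first column)
#'
#' @param d Symmetric dissimilarity matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dissimilarity <- function(d, path) {
  check_dissimilarity(d)
  labels <- rownames(d) %||% as.character(seq_len(nrow(d)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", labels), collapse = "\t"), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(labels[i], sprintf("%.17g", d[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}
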