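#' Read a log2 expression matrix from tab-separated text
#'
#' Expects a header row of sample identifiers, gene identifiers in the first
#' column, and a numeric body on the log2 scale (the package consumes
#' already-normalized values). Input row and column order are preserved.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers).
#' @details Duplicated gene or sample identifiers, and any missing or
#'   non-numeric cell, are errors: the method has no imputation rule and
#'   silent repair would desynchronize gene universes downstream.
#' @seealso [write_expression()] for the exact inverse, [read_metadata()],
#'   [split_by_group()]
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) {
    stop_topohet("expression file not found: %s", path, class = "topohet_io_error")
  }
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    stop_topohet("expression file %s needs a gene-id column plus >= 1 sample column",
                 path, class = "topohet_parse_error")
  }
  gene_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1L]
    stop_topohet("duplicated gene identifier '%s' in %s", dup, path,
                 class = "topohet_identifier_error")
  }
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1L]
    stop_topohet("duplicated sample identifier '%s' in %s", dup, path,
                 class = "topohet_identifier_error")
  }
  values <- matrix(NA_real_, nrow = nrow(tab), ncol = length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- suppressWarnings(as.numeric(tab[[j + 1L]]))
    bad <- which(!is.finite(col))
    if (length(bad)) {
      stop_topohet(
        "non-numeric or missing value '%s' at gene '%s', sample '%s' in %s",
        tab[[j + 1L]][bad[1L]], gene_ids[bad[1L]], sample_ids[j], path,
        class = "topohet_parse_error")
    }
    values[, j] <- col
  }
  values
}

#' Write an expression matrix as tab-separated text
#'
#' Full-precision (`%.17g`) formatting so that a write/read round trip
#' reproduces values bit-exactly.
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  check_expression(expr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
  body <- apply(expr, 1L, function(row) paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(paste(rownames(expr), body, sep = "\t"), con)
  invisible(path)
}

check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop_topohet("expression must be a numeric matrix", class = "topohet_type_error")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop_topohet("expression matrix needs gene rownames and sample colnames",
                 class = "topohet_identifier_error")
  }
  if (anyDuplicated(rownames(expr)) || anyDuplicated(colnames(expr))) {
    stop_topohet("expression identifiers must be unique",
                 class = "topohet_identifier_error")
  }
  if (!all(is.finite(expr))) {
    stop_topohet("expression matrix contains non-finite values",
                 class = "topohet_parse_error")
  }
  invisible(expr)
}

#' Read sample group metadata
#'
#' Two-column CSV `sample_id,group` with a header; exactly two distinct group
#' labels are required.
#'
#' @param path Path to the CSV file.
#' @return Named character vector mapping sample id to group label.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    stop_topohet("metadata file not found: %s", path, class = "topohet_io_error")
  }
  tab <- read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (ncol(tab) < 2L) {
    stop_topohet("metadata must have columns sample_id,group",
                 class = "topohet_parse_error")
  }
  meta <- stats::setNames(tab[[2L]], tab[[1L]])
  check_metadata(meta)
  meta
}

check_metadata <- function(meta) {
  if (anyDuplicated(names(meta))) {
    stop_topohet("duplicated sample id '%s' in metadata",
                 names(meta)[duplicated(names(meta))][1L],
                 class = "topohet_identifier_error")
  }
  labels <- unique(meta)
  if (length(labels) != 2L) {
    stop_topohet("metadata must define exactly two groups (found %d)",
                 length(labels), class = "topohet_metadata_error")
  }
  invisible(meta)
}

# Align metadata to a matrix's samples; enforce the equal-group-size contract.
# Equal sizes are structural to the method: the number of connected components
# of a point cloud depends on the number of points, so unbalanced groups would
# bias every dimension-0 invariant.
match_groups <- function(expr, meta) {
  check_expression(expr)
  check_metadata(meta)
  samples <- colnames(expr)
  missing <- setdiff(samples, names(meta))
  if (length(missing)) {
    stop_topohet("metadata is missing sample(s): %s",
                 paste(missing, collapse = ", "),
                 class = "topohet_metadata_error")
  }
  meta <- meta[samples]
  sizes <- table(meta)
  if (length(sizes) != 2L) {
    stop_topohet("samples of the matrix must span exactly two groups",
                 class = "topohet_metadata_error")
  }
  if (sizes[[1L]] != sizes[[2L]]) {
    stop_topohet(paste0(
      "groups must have equal size (found %d vs %d): the number of connected ",
      "components depends on the number of points, so dimension-0 invariants ",
      "are only comparable between equal-sized clouds"),
      sizes[[1L]], sizes[[2L]], class = "topohet_contract_error")
  }
  meta
}

#' Split an expression matrix into its two groups
#'
#' @param expr Expression matrix (genes x samples).
#' @param meta Named character vector `sample_id -> group label` with exactly
#'   two labels of equal size covering `colnames(expr)`.
#' @return Named list of two matrices (names = group labels in sorted order)
#'   with identical gene rows and disjoint samples covering the input.
#' @export
split_by_group <- function(expr, meta) {
  meta <- match_groups(expr, meta)
  labels <- sort(unique(meta))
  out <- lapply(labels, function(lab) expr[, names(meta)[meta == lab], drop = FALSE])
  names(out) <- labels
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `set_name <TAB> description <TAB> gene ...`.
#' Duplicate genes within a line are deduplicated (first occurrence kept).
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene identifiers, with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop_topohet("GMT file not found: %s", path, class = "topohet_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop_topohet("GMT line %d has %d field(s); need set name, description and >= 1 gene",
                   i, length(fields), class = "topohet_parse_error")
    }
    nms[i] <- fields[1L]
    descs[i] <- fields[2L]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(nms)) {
    stop_topohet("duplicated gene-set name '%s' in %s",
                 nms[duplicated(nms)][1L], path,
                 class = "topohet_identifier_error")
  }
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(descs, nms)
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets Named list of character vectors; an optional `descriptions`
#'   attribute supplies the second column (default `"na"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Drop genes constant across all samples
#'
#' Pre-filter to apply BEFORE group splitting, so that both groups keep the
#' identical gene universe: constant genes have undefined Pearson correlation
#' and would otherwise abort [pearson_dissimilarity()].
#'
#' @param expr Expression matrix.
#' @return The matrix without zero-variance rows; a message reports how many
#'   were removed.
#' @export
drop_constant_genes <- function(expr) {
  check_expression(expr)
  keep <- apply(expr, 1L, function(x) diff(range(x)) > 0)
  if (any(!keep)) {
    message(sprintf("dropping %d constant gene(s)", sum(!keep)))
  }
  expr[keep, , drop = FALSE]
}
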