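#' Summarize a persistence diagram into topological invariants
#'
#' For each dimension `k`, sums the lengths (`SL_k`), birth times (`SBT_k`)
#' and death times (`SDT_k`) of the finite cycles, where a cycle's length is
#' `death - birth`. Essential classes are counted but excluded from the sums
#' (their death is not a finite scale). Since every connected component is
#' born at scale 0, `SBT_0 = 0` and `SL_0 = SDT_0`; `SDT_0` is the package's
#' primary heterogeneity measure — a more dispersed cloud merges later, so its
#' components accumulate larger death times.
#'
#' The Euler characteristic is the alternating sum over dimensions 0-2 only,
#' `chi = SL_0 - SL_1 + SL_2`, regardless of `max_dim` (higher-dimensional
#' cycles are rare and transient in expression clouds); dimension-3 sums are
#' still reported in `per_dim`.
#'
#' @param diagram A `persistence_diagram`.
#' @return An object of class `diagram_summary`: list with `per_dim` (data
#'   frame `dimension, SL, SBT, SDT, n_finite, n_essential`), `chi` and
#'   `max_dim`. Dimensions absent from the diagram contribute zero rows.
#' @export
summarize_diagram <- function(diagram) {
  stopifnot(inherits(diagram, "persistence_diagram"))
  max_dim <- attr(diagram, "max_dim") %||% max(diagram$dimension, 0L)
  dims <- 0:max(max_dim, 2L)
  df <- as.data.frame(diagram)
  # canonical accumulation order for bit-reproducibility
  df <- df[order(df$dimension, df$birth, df$death), , drop = FALSE]
  per <- do.call(rbind, lapply(dims, function(k) {
    rows <- df[df$dimension == k, , drop = FALSE]
    fin <- rows[is.finite(rows$death), , drop = FALSE]
    data.frame(dimension = k,
               SL = sum(fin$death - fin$birth),
               SBT = sum(fin$birth),
               SDT = sum(fin$death),
               n_finite = nrow(fin),
               n_essential = sum(!is.finite(rows$death)))
  }))
  chi <- per$SL[per$dimension == 0L] - per$SL[per$dimension == 1L] +
    per$SL[per$dimension == 2L]
  structure(list(per_dim = per, chi = chi, max_dim = max_dim),
            class = "diagram_summary")
}

#' @export
print.diagram_summary <- function(x, ...) {
  cat("diagram summary (sums over finite cycles)\n")
  print(x$per_dim, row.names = FALSE)
  cat(sprintf("Euler characteristic (dims 0-2): chi = %.6g\n", x$chi))
  invisible(x)
}

#' Sum of death times of connected components
#'
#' Convenience accessor for the dimension-0 heterogeneity invariant of a
#' diagram or summary.
#'
#' @param x A `persistence_diagram` or `diagram_summary`.
#' @return `SDT_0` as a single number.
#' @export
sdt0 <- function(x) {
  if (inherits(x, "persistence_diagram")) x <- summarize_diagram(x)
  stopifnot(inherits(x, "diagram_summary"))
  x$per_dim$SDT[x$per_dim$dimension == 0L]
}

#' Euler characteristic of a diagram
#'
#' @inheritParams sdt0
#' @return `chi = SL_0 - SL_1 + SL_2`.
#' @export
euler_characteristic <- function(x) {
  if (inherits(x, "persistence_diagram")) x <- summarize_diagram(x)
  stopifnot(inherits(x, "diagram_summary"))
  x$chi
}

#' Export a diagram summary as flat JSON
#'
#' `per_dim` is keyed by the dimension as text.
#'
#' @param summary A `diagram_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "diagram_summary"))
  per <- summary$per_dim
  per_dim <- stats::setNames(lapply(seq_len(nrow(per)), function(i) {
    as.list(per[i, c("SL", "SBT", "SDT", "n_finite", "n_essential")])
  }), as.character(per$dimension))
  jsonlite::write_json(list(per_dim = per_dim, chi = summary$chi,
                            max_dim = summary$max_dim),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
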