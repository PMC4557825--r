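#' Build a cell-type-specific weighted interactome
#'
#' Re-weights a generic protein-interaction network with one cell type's
#' percentile expression scores: the edge between genes i and j gets weight
#' `w[i, j] = x[i] * x[j]`, the product of the two percentile scores. No
#' expression cutoff is applied, so edges are kept even at weight 0;
#' vertices without an expression score are removed (their edges with
#' them), with the dropped counts reported via `message()`.
#'
#' @param edges Edge list: a tibble/data frame whose first two columns hold
#'   the interacting gene identifiers (e.g. from [read_string_links()]).
#' @param profile Percentile scores for one cell type: either a named
#'   numeric vector, or a gene x cell-type matrix together with
#'   `cell_type` naming the column to use.
#' @param cell_type Column of `profile` to use when `profile` is a matrix;
#'   also stored on the result for bookkeeping.
#' @return A `cell_interactome` object: vertex identifiers, an m x 2 edge
#'   index matrix, edge weights in `[0, 1]` and the cell type id.
#' @export
build_cell_interactome <- function(edges, profile, cell_type = NULL) {
  if (is.matrix(profile)) {
    if (is.null(cell_type)) {
      if (ncol(profile) != 1L) {
        stop("profile has several columns; name one via cell_type")
      }
      cell_type <- colnames(profile)[[1L]]
    }
    x <- profile[, cell_type]
  } else {
    x <- profile
  }
  if (is.null(names(x))) stop("profile must carry gene names")
  if (any(x < 0 | x > 1)) stop("percentile scores must lie in [0, 1]")

  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  scored <- a %in% names(x) & b %in% names(x)
  if (any(!scored)) {
    message(sum(!scored), " edge(s) dropped: endpoint without expression score")
  }
  a <- a[scored]; b <- b[scored]
  if (length(a) == 0L) stop("empty interactome: no edge has scored endpoints")

  vertices <- sort(unique(c(a, b)))
  ia <- match(a, vertices)
  ib <- match(b, vertices)
  # canonical undirected orientation + deduplication
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  dedup <- !duplicated(lo * (length(vertices) + 1) + hi)
  lo <- lo[dedup]; hi <- hi[dedup]
  xs <- x[vertices]

  structure(
    list(
      vertices = vertices,
      edges = cbind(from = lo, to = hi),
      weight = unname(xs[lo] * xs[hi]),
      scores = unname(xs),
      cell_type = cell_type %||% "cell_type"
    ),
    class = "cell_interactome"
  )
}

#' @export
print.cell_interactome <- function(x, ...) {
  cat("<cell_interactome> ", x$cell_type, ": ", length(x$vertices),
      " vertices, ", nrow(x$edges), " edges, weights in [",
      signif(min(x$weight), 3), ", ", signif(max(x$weight), 3), "]\n",
      sep = "")
  invisible(x)
}

# Replace edge weights using a new score vector over the same topology.
# Used by the permutation tests: observed and permuted interactomes share
# every vertex and edge and differ only in weights.
reweight_interactome <- function(graph, x) {
  xs <- x[graph$vertices]
  if (anyNA(xs)) stop("new scores miss some interactome vertices")
  graph$weight <- unname(xs[graph$edges[, 1L]] * xs[graph$edges[, 2L]])
  graph$scores <- unname(xs)
  graph
}
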