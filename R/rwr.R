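#' Random walk with restart probabilities
#'
#' Iterates `p_{t+1} = (1 - r) A p_t + r p_0` where `A` is the
#' column-normalized weighted adjacency matrix of the interactome and `p_0`
#' holds one identity column per source vertex, until the Manhattan
#' distance between successive restricted probability matrices falls below
#' `tol`. Only the columns for the requested sources are computed. A vertex
#' with zero total incident weight (a dangling column of `A`) sends the
#' walker back to its start vertex, so every column keeps summing to 1.
#'
#' @param graph A `cell_interactome`.
#' @param sources Character vector of source vertices (must be in the
#'   graph).
#' @param r Restart probability in (0, 1] (default 0.7).
#' @param tol Convergence cutoff on the Manhattan distance; defaults to
#'   `length(sources) * 1e-5`.
#' @param max_iter Iteration cap (default 10000).
#' @return An n x length(sources) matrix of steady-state probabilities;
#'   each column sums to 1.
#' @export
rwr_probabilities <- function(graph, sources, r = 0.7, tol = NULL,
                              max_iter = 10000L) {
  stopifnot(inherits(graph, "cell_interactome"))
  if (r <= 0 || r > 1) stop("restart probability must lie in (0, 1]")
  missing <- setdiff(sources, graph$vertices)
  if (length(missing) > 0L) {
    stop("source(s) not in graph: ", paste(missing, collapse = ", "))
  }
  if (all(graph$weight <= 0)) {
    stop("graph has no positive-weight edge")
  }
  if (is.null(tol)) tol <- length(sources) * 1e-5
  if (tol <= 0) stop("tol must be positive")

  n <- length(graph$vertices)
  A <- matrix(0, n, n)
  e <- graph$edges
  A[e] <- graph$weight
  A[e[, c(2L, 1L), drop = FALSE]] <- graph$weight
  col_tot <- colSums(A)
  dangling <- col_tot == 0
  col_tot[dangling] <- 1
  A <- sweep(A, 2L, col_tot, "/")

  src <- match(sources, graph$vertices)
  p0 <- matrix(0, n, length(src))
  p0[cbind(src, seq_along(src))] <- 1

  p <- p0
  converged <- FALSE
  residual <- NA_real_
  for (iter in seq_len(max_iter)) {
    pn <- (1 - r) * (A %*% p) + r * p0
    if (any(dangling)) {
      lost <- colSums(p[dangling, , drop = FALSE])
      pn <- pn + (1 - r) * sweep(p0, 2L, lost, "*")
    }
    residual <- sum(abs(pn - p))
    p <- pn
    if (residual < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("random walk did not converge within ", max_iter,
         " iterations (last residual ", signif(residual, 4), ")")
  }
  dimnames(p) <- list(graph$vertices, sources)
  p
}

#' Convert random-walk probabilities to ranked distances
#'
#' Per source, vertices are ranked by steady-state probability in
#' descending order: the vertex the walker is most likely to occupy gets
#' rank 1. Ties receive the average of their rank positions. These ranks
#' serve as network distances.
#'
#' @param probabilities Matrix from [rwr_probabilities()] (rows vertices,
#'   one column per source).
#' @return Matrix of the same shape whose entry `[j, i]` is the ranked
#'   distance from source i to vertex j.
#' @export
ranked_distances <- function(probabilities) {
  out <- apply(probabilities, 2, function(col) {
    rank(-col, ties.method = "average")
  })
  dimnames(out) <- dimnames(probabilities)
  out
}

# Ranked distances restricted to the source rows, avoiding a full sort:
# returns the |S| x |S| matrix D[i, j] = rank of vertex j for source i.
ranked_distances_among <- function(probabilities, sources) {
  idx <- match(sources, rownames(probabilities))
  s <- length(sources)
  D <- matrix(0, s, s, dimnames = list(sources, sources))
  for (i in seq_len(s)) {
    col <- probabilities[, i]
    v <- col[idx]
    for (j in seq_len(s)) {
      D[i, j] <- sum(col > v[[j]]) + (sum(col == v[[j]]) + 1) / 2
    }
  }
  D
}
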