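# In-code fixtures shared across test files.

`%||%` <- function(x, y) if (is.null(x)) y else x

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Small STRING-dialect protein links file (scores on the 0-1000 scale).
string_links_lines <- c(
  "protein1 protein2 neighborhood experimental textmining combined_score",
  "P1 P2 0 850 100 860",
  "P2 P3 0 800 0 800",
  "P3 P4 0 0 900 900",
  "P1 P4 0 900 0 905",
  "P4 P1 0 820 50 830",   # reverse orientation of P1-P4, lower score
  "P5 P5 0 999 0 999"     # self-link, must be dropped
)

# Random weighted interactome for oracle comparisons: every vertex gets a
# strictly positive score so no dangling columns arise.
random_interactome <- function(n, m, seed) {
  set.seed(seed)
  g <- igraph::sample_gnm(n, m)
  el <- igraph::as_edgelist(g)
  genes <- sprintf("v%03d", seq_len(n))
  edges <- tibble::tibble(protein_a = genes[pmin(el[, 1], el[, 2])],
                          protein_b = genes[pmax(el[, 1], el[, 2])])
  scores <- stats::setNames(stats::runif(n, 0.05, 1), genes)
  build_cell_interactome(edges, scores, cell_type = "fixture")
}

# Direct linear solve for the random-walk steady state:
# p = r (I - (1 - r) A)^-1 p0, the closed form the iteration approximates.
direct_rwr <- function(graph, sources, r) {
  n <- length(graph$vertices)
  A <- matrix(0, n, n)
  e <- graph$edges
  A[e] <- graph$weight
  A[e[, c(2, 1), drop = FALSE]] <- graph$weight
  A <- sweep(A, 2, colSums(A), "/")
  src <- match(sources, graph$vertices)
  p0 <- matrix(0, n, length(src))
  p0[cbind(src, seq_along(src))] <- 1
  p <- r * solve(diag(n) - (1 - r) * A, p0)
  dimnames(p) <- list(graph$vertices, sources)
  p
}

# Brute-force compactness: explicit double loop over ordered pairs with
# ranks recomputed by counting, independent of the package's ranking path.
brute_compactness <- function(members, probabilities) {
  s <- length(members)
  total <- 0
  for (i in seq_len(s)) {
    col <- probabilities[, members[[i]]]
    for (j in seq_len(s)) {
      v <- col[[members[[j]]]]
      rank_j <- sum(col > v) + (sum(col == v) + 1) / 2
      total <- total + rank_j
    }
  }
  total / s^2
}

# Exhaustive one-tailed Fisher tail by direct hypergeometric summation
# (safe for small corpora only).
exhaustive_fisher_tail <- function(n_both, n_disease_only, n_cell_only,
                                   n_rest) {
  m <- n_both + n_disease_only
  k <- n_both + n_cell_only
  total <- n_both + n_disease_only + n_cell_only + n_rest
  sum(stats::dhyper(n_both:min(m, k), m, total - m, k))
}
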