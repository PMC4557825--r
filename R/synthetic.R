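#' Generate a synthetic study with planted disease modules
#'
#' Emulates the statistical structure the compactness method assumes: a
#' random background interaction network, and for each simulated disease a
#' densely wired gene module that is overexpressed in one target cell type.
#' Percentile score columns are exact uniform grids (`0, 1/(n-1), ..., 1`)
#' randomly assigned to genes; in the target cell type the module genes are
#' guaranteed scores at or above `overexpression_quantile`. Gene sets are
#' the module members and `truth` records the (disease, target cell type)
#' pairs.
#'
#' With `expression_mode = "counts"`, negative-binomial counts are
#' generated instead (module genes boosted in the target cell type) and the
#' profiles are derived through the full normalization chain
#' ([rle_normalize()], [relative_expression()], [percentile_scores()]); the
#' top-decile guarantee then holds only in expectation.
#'
#' @param n_genes Number of genes (default 300).
#' @param n_cell_types Number of cell types (default 8).
#' @param background_edges Number of Erdős–Rényi background edges
#'   (default 1200).
#' @param module_size Genes per planted module (default 10).
#' @param module_extra_density Probability of wiring each within-module
#'   pair (default 0.6).
#' @param overexpression_quantile Module genes sit at or above this
#'   percentile in the target cell type (default 0.9).
#' @param n_diseases Number of planted diseases; modules are disjoint
#'   (default 5).
#' @param seed Integer seed; the study is fully reproducible from it.
#' @param expression_mode `"scores"` (direct percentile grids, default) or
#'   `"counts"` (negative-binomial counts through the normalization chain).
#' @return A `synthetic_study` object: `profiles` (gene x cell-type
#'   percentile scores), `expression` (counts; only for `"counts"` mode),
#'   `edges` (tibble `protein_a`, `protein_b`, `score`), `gene_sets`
#'   (named list), `truth` (an [association_set()]), `params`.
#' @export
generate_synthetic_study <- function(n_genes = 300L, n_cell_types = 8L,
                                     background_edges = 1200L,
                                     module_size = 10L,
                                     module_extra_density = 0.6,
                                     overexpression_quantile = 0.9,
                                     n_diseases = 5L, seed,
                                     expression_mode = c("scores",
                                                         "counts")) {
  expression_mode <- match.arg(expression_mode)
  if (module_size >= n_genes) stop("module_size must be < n_genes")
  if (overexpression_quantile <= 0 || overexpression_quantile >= 1) {
    stop("overexpression_quantile must lie in (0, 1)")
  }
  if (n_diseases * module_size > n_genes) {
    stop("infeasible: disjoint modules need n_diseases * module_size <= ",
         "n_genes")
  }
  grid <- (0:(n_genes - 1L)) / (n_genes - 1L)
  if (sum(grid >= overexpression_quantile) < module_size) {
    stop("infeasible: fewer than module_size score slots at or above the ",
         "overexpression quantile")
  }
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  cell_types <- sprintf("cell_type_%02d", seq_len(n_cell_types))

  module_genes <- matrix(sample(genes, n_diseases * module_size),
                         nrow = module_size)
  gene_sets <- lapply(seq_len(n_diseases), function(d) {
    sort(module_genes[, d])
  })
  names(gene_sets) <- sprintf("disease_%02d", seq_len(n_diseases))
  # distinct targets when possible: a shared target column must hold every
  # colliding module above the overexpression quantile, which quickly
  # exhausts the top score slots
  targets <- sample(cell_types, n_diseases,
                    replace = n_diseases > n_cell_types)

  # background graph
  bg <- igraph::sample_gnm(n_genes, background_edges)
  el <- igraph::as_edgelist(bg)
  edge_a <- genes[pmin(el[, 1L], el[, 2L])]
  edge_b <- genes[pmax(el[, 1L], el[, 2L])]
  # planted module wiring
  for (d in seq_len(n_diseases)) {
    pairs <- utils::combn(sort(module_genes[, d]), 2L)
    wired <- stats::runif(ncol(pairs)) < module_extra_density
    edge_a <- c(edge_a, pairs[1L, wired])
    edge_b <- c(edge_b, pairs[2L, wired])
  }
  edges <- dplyr::distinct(tibble::tibble(protein_a = edge_a,
                                          protein_b = edge_b))
  edges <- dplyr::arrange(edges, .data$protein_a, .data$protein_b)
  edges$score <- 1

  for (d in seq_len(n_diseases)) {
    dens <- module_density(edges, gene_sets[[d]])
    bg_dens <- nrow(edges) / choose(n_genes, 2L)
    if (dens <= bg_dens) {
      stop("infeasible: planted module density (", signif(dens, 3),
           ") does not exceed background density (", signif(bg_dens, 3), ")")
    }
  }

  if (expression_mode == "scores") {
    profiles <- vapply(cell_types, function(l) sample(grid),
                       numeric(n_genes))
    rownames(profiles) <- genes
    # plant jointly per target column so colliding modules cannot displace
    # each other's top scores
    for (l in unique(targets)) {
      idx <- match(unlist(gene_sets[targets == l], use.names = FALSE),
                   genes)
      if (length(idx) > sum(grid >= overexpression_quantile)) {
        stop("infeasible: modules sharing target cell type '", l,
             "' need more top score slots than available")
      }
      profiles[, l] <- plant_top_scores(profiles[, l], idx,
                                        overexpression_quantile)
    }
    expression <- NULL
  } else {
    mu <- matrix(stats::rgamma(n_genes, shape = 1.2, rate = 1 / 50),
                 n_genes, n_cell_types)
    for (d in seq_len(n_diseases)) {
      idx <- match(gene_sets[[d]], genes)
      mu[idx, match(targets[[d]], cell_types)] <-
        mu[idx, match(targets[[d]], cell_types)] * 50
    }
    expression <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu), size = 5),
      n_genes, n_cell_types, dimnames = list(genes, cell_types)
    )
    profiles <- percentile_scores(
      relative_expression(rle_normalize(expression))
    )
  }

  truth <- association_set(
    tibble::tibble(disease = names(gene_sets), cell_type = targets),
    diseases = names(gene_sets), cell_types = cell_types
  )
  structure(
    list(profiles = profiles, expression = expression, edges = edges,
         gene_sets = gene_sets, truth = truth,
         params = list(n_genes = n_genes, n_cell_types = n_cell_types,
                       background_edges = background_edges,
                       module_size = module_size,
                       module_extra_density = module_extra_density,
                       overexpression_quantile = overexpression_quantile,
                       n_diseases = n_diseases, seed = seed,
                       expression_mode = expression_mode)),
    class = "synthetic_study"
  )
}

# Swap scores within one column so that the genes at module_idx all hold
# values >= quantile; the column stays an exact permutation of the grid.
plant_top_scores <- function(values, module_idx, quantile) {
  need <- module_idx[values[module_idx] < quantile]
  donors <- setdiff(which(values >= quantile), module_idx)
  donors <- donors[sample.int(length(donors))][seq_along(need)]
  tmp <- values[need]
  values[need] <- values[donors]
  values[donors] <- tmp
  values
}

module_density <- function(edges, members) {
  inside <- edges$protein_a %in% members & edges$protein_b %in% members
  sum(inside) / choose(length(members), 2L)
}

#' Generate a null synthetic study (no planted structure)
#'
#' Expression scores are independent uniform percentile grids per cell
#' type, the interaction network is pure Erdős–Rényi background and gene
#' sets are uniform random draws, so no disease is genuinely associated
#' with any cell type. Used for permutation-test calibration.
#'
#' @param n_genes Number of genes (default 150).
#' @param n_cell_types Number of cell types (default 4).
#' @param background_edges Number of background edges (default 600).
#' @param set_size Genes per random gene set (default 8).
#' @param n_sets Number of gene sets (default 1).
#' @param seed Integer seed.
#' @return A `synthetic_study` object with an empty `truth` set.
#' @export
generate_null_study <- function(n_genes = 150L, n_cell_types = 4L,
                                background_edges = 600L, set_size = 8L,
                                n_sets = 1L, seed) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  cell_types <- sprintf("cell_type_%02d", seq_len(n_cell_types))
  grid <- (0:(n_genes - 1L)) / (n_genes - 1L)
  profiles <- vapply(cell_types, function(l) sample(grid), numeric(n_genes))
  rownames(profiles) <- genes
  bg <- igraph::sample_gnm(n_genes, background_edges)
  el <- igraph::as_edgelist(bg)
  edges <- tibble::tibble(protein_a = genes[pmin(el[, 1L], el[, 2L])],
                          protein_b = genes[pmax(el[, 1L], el[, 2L])])
  edges <- dplyr::arrange(dplyr::distinct(edges),
                          .data$protein_a, .data$protein_b)
  edges$score <- 1
  gene_sets <- lapply(seq_len(n_sets), function(d) sort(sample(genes,
                                                               set_size)))
  names(gene_sets) <- sprintf("disease_%02d", seq_len(n_sets))
  truth <- association_set(
    tibble::tibble(disease = character(0), cell_type = character(0)),
    diseases = names(gene_sets), cell_types = cell_types
  )
  structure(
    list(profiles = profiles, expression = NULL, edges = edges,
         gene_sets = gene_sets, truth = truth,
         params = list(n_genes = n_genes, n_cell_types = n_cell_types,
                       background_edges = background_edges,
                       set_size = set_size, n_sets = n_sets, seed = seed,
                       expression_mode = "scores")),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", nrow(x$profiles), " genes x ",
      ncol(x$profiles), " cell types, ", nrow(x$edges), " edges, ",
      length(x$gene_sets), " gene set(s), ", nrow(x$truth$pairs),
      " planted association(s)\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to disk in the pipeline's file formats
#'
#' Writes the percentile profiles (TSV matrix), the edge list (TSV), the
#' gene sets (GMT) and the planted truth (TSV) into a directory.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    profiles = file.path(dir, "profiles.tsv"),
    expression = file.path(dir, "expression.tsv"),
    edges = file.path(dir, "edges.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.tsv")
  )
  write_expression_matrix(study$profiles, paths[["profiles"]])
  if (!is.null(study$expression)) {
    write_expression_matrix(study$expression, paths[["expression"]])
  } else {
    paths <- paths[names(paths) != "expression"]
  }
  utils::write.table(study$edges, paths[["edges"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gene_sets(study$gene_sets, paths[["gene_sets"]])
  utils::write.table(study$truth$pairs, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
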