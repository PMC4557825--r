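#' Compactness of a gene set on a ranked-distance matrix
#'
#' The compactness score is the mean ranked random-walk distance over all
#' ordered pairs of the set's vertices, `C(S, G) = sum_{i,j in S} d(i, j) /
#' |S|^2`. Smaller values mean the set clusters more tightly in the graph.
#' Self-pairs (i = i) are part of the |S|^2 denominator and are included by
#' default; `include_self = FALSE` excludes them (denominator
#' `|S| (|S| - 1)`) for sensitivity analysis.
#'
#' @param set Character vector of gene identifiers.
#' @param distances Ranked-distance matrix from [ranked_distances()] whose
#'   columns cover the set members as sources.
#' @param include_self Include i = i pairs (default TRUE).
#' @return The compactness score, a positive number.
#' @export
compactness <- function(set, distances, include_self = TRUE) {
  set <- unique(as.character(set))
  present <- set[set %in% colnames(distances) & set %in% rownames(distances)]
  if (length(present) < length(set)) {
    warning(length(set) - length(present),
            " gene(s) absent from the distance matrix dropped")
  }
  s <- length(present)
  if (s < 2L) stop("compactness needs at least 2 genes present in the graph")
  sub <- distances[present, present, drop = FALSE]
  if (include_self) {
    sum(sub) / s^2
  } else {
    (sum(sub) - sum(diag(sub))) / (s * (s - 1))
  }
}

#' Empirical permutation P value with a 1/u floor
#'
#' The proportion of permuted statistics strictly more extreme than the
#' observed one, floored at `1/u` so no P value equals zero.
#'
#' @param observed Observed statistic.
#' @param permuted Numeric vector of `u` permuted statistics.
#' @param direction `"smaller_is_extreme"` (compactness-style) or
#'   `"greater_is_extreme"` (overexpression-style).
#' @param u Number of permutations; must equal `length(permuted)`.
#' @return A P value in `[1/u, 1]`.
#' @export
empirical_p <- function(observed, permuted,
                        direction = c("smaller_is_extreme",
                                      "greater_is_extreme"),
                        u = length(permuted)) {
  direction <- match.arg(direction)
  if (u < 1L) stop("u must be at least 1")
  if (length(permuted) != u) {
    stop("length(permuted) (", length(permuted), ") must equal u (", u, ")")
  }
  k <- if (direction == "smaller_is_extreme") {
    sum(permuted < observed)
  } else {
    sum(permuted > observed)
  }
  max(k / u, 1 / u)
}

new_association_test <- function(rows, method, u, r = NA_real_,
                                 seed = NULL) {
  out <- tibble::as_tibble(rows)
  class(out) <- c("association_test", class(out))
  attr(out, "method") <- method
  attr(out, "u") <- as.integer(u)
  attr(out, "r") <- r
  attr(out, "seed") <- seed
  out
}

#' Gene set compactness (GSC) test
#'
#' For each cell type, builds the cell-type-specific interactome, measures
#' the compactness of the disease gene set with ranked random-walk
#' distances, and compares it with compactness scores from `u` interactomes
#' rebuilt from permuted expression profiles on the same topology. The
#' empirical P value is the proportion of permuted interactomes with a
#' *smaller* compactness (tighter clustering) than observed, floored at
#' `1/u`.
#'
#' Permuted profiles are drawn once per disease and reused across cell
#' types (a permuted interactome is built from a single permuted column, so
#' it is the same graph whichever cell type is being tested);
#' `reuse_permutations = FALSE` draws an independent stream per cell type.
#'
#' @param sets A character vector (one gene set) or a named list of
#'   character vectors (one per disease).
#' @param edges Edge list (first two columns: interacting gene ids).
#' @param profiles Gene x cell-type matrix of percentile scores.
#' @param u Number of permutations (default 10000).
#' @param r Restart probability (default 0.7).
#' @param tol Convergence cutoff; defaults to `|S| * 1e-5`.
#' @param max_iter Iteration cap for the random walk.
#' @param seed Optional integer seed.
#' @param reuse_permutations Share the permuted-profile stream across cell
#'   types (default TRUE).
#' @param permute_method Permutation scheme, see [permute_profiles()].
#' @param include_self Passed to [compactness()].
#' @return An `association_test` tibble with one row per (disease, cell
#'   type): `disease`, `cell_type`, `statistic` (observed compactness),
#'   `p_value`, `perm_mean`, `perm_sd`.
#' @export
gsc_test <- function(sets, edges, profiles, u = 10000L, r = 0.7,
                     tol = NULL, max_iter = 10000L, seed = NULL,
                     reuse_permutations = TRUE,
                     permute_method = c("column", "per_gene"),
                     include_self = TRUE) {
  permute_method <- match.arg(permute_method)
  single <- !is.list(sets)
  if (single) sets <- list(disease = sets)
  if (is.null(names(sets))) {
    names(sets) <- paste0("disease_", seq_along(sets))
  }
  if (!is.null(seed)) set.seed(seed)
  cell_types <- colnames(profiles)
  base <- build_cell_interactome(edges, profiles, cell_type = cell_types[[1L]])
  vertices <- base$vertices

  eval_set <- function(graph, members) {
    p <- rwr_probabilities(graph, members, r = r, tol = tol,
                           max_iter = max_iter)
    D <- ranked_distances_among(p, members)
    if (include_self) {
      mean(D)
    } else {
      (sum(D) - sum(diag(D))) / (length(members) * (length(members) - 1))
    }
  }

  rows <- list()
  for (disease in names(sets)) {
    members <- intersect(unique(sets[[disease]]), vertices)
    if (length(members) < 2L) {
      msg <- paste0("gene set '", disease,
                    "' has fewer than 2 genes in the interactome")
      if (single) stop(msg)
      warning(msg, "; skipped")
      next
    }
    observed <- vapply(cell_types, function(l) {
      eval_set(reweight_interactome(base, profiles[vertices, l]), members)
    }, numeric(1L))
    if (reuse_permutations) {
      permuted <- vapply(seq_len(u), function(b) {
        xp <- permute_profiles(profiles, method = permute_method)[, 1L]
        eval_set(reweight_interactome(base, xp[vertices]), members)
      }, numeric(1L))
      perm_of <- function(l) permuted
    } else {
      streams <- lapply(cell_types, function(l) {
        vapply(seq_len(u), function(b) {
          xp <- permute_profiles(profiles, method = permute_method)[, 1L]
          eval_set(reweight_interactome(base, xp[vertices]), members)
        }, numeric(1L))
      })
      names(streams) <- cell_types
      perm_of <- function(l) streams[[l]]
    }
    rows[[disease]] <- tibble::tibble(
      disease = disease,
      cell_type = cell_types,
      statistic = unname(observed),
      p_value = vapply(cell_types, function(l) {
        empirical_p(observed[[l]], perm_of(l), "smaller_is_extreme", u)
      }, numeric(1L)),
      perm_mean = vapply(cell_types, function(l) mean(perm_of(l)),
                         numeric(1L)),
      perm_sd = vapply(cell_types, function(l) stats::sd(perm_of(l)),
                       numeric(1L))
    )
  }
  if (length(rows) == 0L) stop("no testable gene set")
  new_association_test(dplyr::bind_rows(rows), "gsc", u, r, seed)
}

#' Gene set overexpression (GSO) test
#'
#' For each cell type, the observed statistic is the mean percentile
#' expression score of the gene set; it is compared with the mean score of
#' the set in `u` permuted expression profiles. The empirical P value is
#' the proportion of permuted profiles with a *greater* mean score, floored
#' at `1/u`.
#'
#' @inheritParams gsc_test
#' @return An `association_test` tibble with one row per (disease, cell
#'   type).
#' @export
gso_test <- function(sets, profiles, u = 10000L, seed = NULL,
                     reuse_permutations = TRUE,
                     permute_method = c("column", "per_gene")) {
  permute_method <- match.arg(permute_method)
  single <- !is.list(sets)
  if (single) sets <- list(disease = sets)
  if (is.null(names(sets))) {
    names(sets) <- paste0("disease_", seq_along(sets))
  }
  if (!is.null(seed)) set.seed(seed)
  cell_types <- colnames(profiles)
  rows <- list()
  for (disease in names(sets)) {
    members <- intersect(unique(sets[[disease]]), rownames(profiles))
    if (length(members) < 1L) {
      stop("gene set '", disease, "' shares no gene with the profiles")
    }
    observed <- colMeans(profiles[members, cell_types, drop = FALSE])
    if (reuse_permutations) {
      permuted <- vapply(seq_len(u), function(b) {
        mean(permute_profiles(profiles, method = permute_method)[members, 1L])
      }, numeric(1L))
      perm_of <- function(l) permuted
    } else {
      streams <- lapply(cell_types, function(l) {
        vapply(seq_len(u), function(b) {
          mean(permute_profiles(profiles,
                                method = permute_method)[members, 1L])
        }, numeric(1L))
      })
      names(streams) <- cell_types
      perm_of <- function(l) streams[[l]]
    }
    rows[[disease]] <- tibble::tibble(
      disease = disease,
      cell_type = cell_types,
      statistic = unname(observed),
      p_value = vapply(cell_types, function(l) {
        empirical_p(observed[[l]], perm_of(l), "greater_is_extreme", u)
      }, numeric(1L)),
      perm_mean = vapply(cell_types, function(l) mean(perm_of(l)),
                         numeric(1L)),
      perm_sd = vapply(cell_types, function(l) stats::sd(perm_of(l)),
                       numeric(1L))
    )
  }
  new_association_test(dplyr::bind_rows(rows), "gso", u, NA_real_, seed)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH q values. Input P values must lie in (0, 1].
#'
#' @param p_values Numeric vector of P values.
#' @return Vector of q values, same length.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Add BH q values to an association table
#'
#' @param results Association table with a `p_value` column.
#' @param scope `"global"` adjusts across the whole disease x cell-type
#'   matrix; `"by_disease"` adjusts within each disease.
#' @return The table with a `q_value` column added (attributes preserved).
#' @export
adjust_fdr <- function(results, scope = c("global", "by_disease")) {
  scope <- match.arg(scope)
  if (scope == "global") {
    results$q_value <- bh_adjust(results$p_value)
  } else {
    results$q_value <- stats::ave(results$p_value, results$disease,
                                  FUN = bh_adjust)
  }
  results
}

#' Rank cell types within each disease
#'
#' Orders cell types by P value; ties are broken by the standardized effect
#' size `(statistic - perm_mean) / perm_sd` (ascending for the compactness
#' test, where smaller statistics are more extreme; descending for the
#' overexpression test), then lexicographically.
#'
#' @param results An `association_test` table.
#' @return The table with a `rank` column, ordered within disease.
#' @export
rank_cell_types <- function(results) {
  method <- attr(results, "method") %||% "gsc"
  sign <- if (identical(method, "gso")) -1 else 1
  z <- sign * (results$statistic - results$perm_mean) /
    ifelse(results$perm_sd > 0, results$perm_sd, Inf)
  out <- results[order(results$disease, results$p_value, z,
                       results$cell_type), ]
  out$rank <- stats::ave(seq_len(nrow(out)), out$disease,
                         FUN = seq_along)
  out
}

#' High-weight edge enrichment of a disease sub-network
#'
#' The sub-network holds the gene set's vertices plus their direct
#' interaction partners (induced subgraph). The weight threshold is the
#' given quantile of *all* edge weights in the full cell-type interactome;
#' the statistic is the number of sub-network edges strictly above it.
#' Permutations shuffle the cell type's gene-to-score assignment,
#' recompute the sub-network weights on the same topology and recount; the
#' P value is the proportion of permutations with a greater count, floored
#' at `1/u`.
#'
#' @param set Character vector of gene identifiers.
#' @param graph A `cell_interactome`.
#' @param quantile Quantile of the full interactome's edge weights used as
#'   threshold (default 0.99, the top 1%).
#' @param u Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `count`, `threshold`, `p_value`,
#'   `n_vertices`, `n_edges` (sub-network size), `u`.
#' @export
subnetwork_weight_enrichment <- function(set, graph, quantile = 0.99,
                                         u = 10000L, seed = NULL) {
  stopifnot(inherits(graph, "cell_interactome"))
  if (!is.null(seed)) set.seed(seed)
  members_idx <- which(graph$vertices %in% set)
  if (length(members_idx) == 0L) {
    stop("empty sub-network: no gene of the set is in the graph")
  }
  touches <- graph$edges[, 1L] %in% members_idx |
    graph$edges[, 2L] %in% members_idx
  sub_vertices <- union(members_idx,
                        unique(as.vector(graph$edges[touches, ])))
  in_sub <- graph$edges[, 1L] %in% sub_vertices &
    graph$edges[, 2L] %in% sub_vertices
  if (!any(in_sub)) stop("empty sub-network: the set has no interactions")
  threshold <- stats::quantile(graph$weight, quantile, names = FALSE)
  sub_edges <- graph$edges[in_sub, , drop = FALSE]
  x <- graph$scores
  observed <- sum(x[sub_edges[, 1L]] * x[sub_edges[, 2L]] > threshold)
  permuted <- vapply(seq_len(u), function(b) {
    xp <- x[sample.int(length(x))]
    sum(xp[sub_edges[, 1L]] * xp[sub_edges[, 2L]] > threshold)
  }, numeric(1L))
  tibble::tibble(
    count = observed,
    threshold = threshold,
    p_value = empirical_p(observed, permuted, "greater_is_extreme", u),
    n_vertices = length(sub_vertices),
    n_edges = nrow(sub_edges),
    u = u
  )
}

#' Keep gene sets with enough members
#'
#' @param sets Named list of character vectors.
#' @param min_genes Minimum set size (default 6).
#' @return The filtered list.
#' @export
filter_gene_sets <- function(sets, min_genes = 6L) {
  sets[lengths(sets) >= min_genes]
}
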