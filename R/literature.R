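#' One-tailed Fisher's exact enrichment P value, computed in log space
#'
#' Upper tail of the hypergeometric distribution for the 2x2 table
#' `(n_both, n_disease_only, n_cell_only, n_rest)`: the probability of
#' co-mentioning at least as many articles as observed given the margins.
#' The tail is accumulated with a log-sum-exp over log hypergeometric
#' masses, so values far below the double underflow of naive summation of
#' individual factorials remain exact.
#'
#' @param n_both,n_disease_only,n_cell_only,n_rest Cell counts of the 2x2
#'   contingency table.
#' @param log_p Return the natural log of the P value instead.
#' @return The one-tailed P value (or its log).
#' @export
fisher_enrichment_test <- function(n_both, n_disease_only, n_cell_only,
                                   n_rest, log_p = FALSE) {
  counts <- c(n_both, n_disease_only, n_cell_only, n_rest)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be nonnegative integers")
  }
  m <- n_both + n_disease_only      # articles mentioning the disease
  k <- n_both + n_cell_only         # articles mentioning the cell type
  total <- sum(counts)
  hi <- min(m, k)
  if (n_both > hi) stop("inconsistent contingency table")
  ks <- n_both:hi
  log_masses <- stats::dhyper(ks, m, total - m, k, log = TRUE)
  mx <- max(log_masses)
  lp <- mx + log(sum(exp(log_masses - mx)))
  lp <- min(lp, 0)
  if (log_p) lp else exp(lp)
}

#' Literature co-occurrence significance
#'
#' Applies the one-tailed Fisher's exact test to each (disease, cell type)
#' pair of a co-occurrence count table: is the number of articles
#' co-mentioning the two terms greater than expected from the numbers of
#' articles mentioning each term individually?
#'
#' @param table Tibble with columns `disease`, `cell_type`, `n_both`,
#'   `n_disease_only`, `n_cell_only`, `corpus_size`.
#' @return The table with `p_value` (and `log_p`) columns added.
#' @export
cooccurrence_fisher <- function(table) {
  required <- c("disease", "cell_type", "n_both", "n_disease_only",
                "n_cell_only", "corpus_size")
  missing <- setdiff(required, colnames(table))
  if (length(missing) > 0L) {
    stop("co-occurrence table misses column(s): ",
         paste(missing, collapse = ", "))
  }
  mentioned <- table$n_both + table$n_disease_only + table$n_cell_only
  bad <- which(table$n_both < 0 | table$n_disease_only < 0 |
                 table$n_cell_only < 0 | mentioned > table$corpus_size)
  if (length(bad) > 0L) {
    stop("inconsistent counts for pair (", table$disease[bad[1L]], ", ",
         table$cell_type[bad[1L]], ")")
  }
  log_p <- vapply(seq_len(nrow(table)), function(i) {
    fisher_enrichment_test(
      table$n_both[[i]], table$n_disease_only[[i]], table$n_cell_only[[i]],
      table$corpus_size[[i]] - mentioned[[i]], log_p = TRUE
    )
  }, numeric(1L))
  table$log_p <- log_p
  table$p_value <- exp(log_p)
  table
}

#' Construct an association set over a disease x cell-type universe
#'
#' @param pairs Tibble/data frame with columns `disease` and `cell_type`
#'   (duplicates collapsed).
#' @param diseases,cell_types Character vectors spanning the universe.
#' @return An `association_set` object.
#' @export
association_set <- function(pairs, diseases, cell_types) {
  pairs <- unique(tibble::as_tibble(pairs)[c("disease", "cell_type")])
  outside <- !(pairs$disease %in% diseases & pairs$cell_type %in% cell_types)
  if (any(outside)) {
    stop(sum(outside), " pair(s) outside the stated universe")
  }
  structure(
    list(pairs = pairs,
         diseases = sort(unique(diseases)),
         cell_types = sort(unique(cell_types))),
    class = "association_set"
  )
}

#' @export
print.association_set <- function(x, ...) {
  cat("<association_set> ", nrow(x$pairs), " pairs over ",
      length(x$diseases), " diseases x ", length(x$cell_types),
      " cell types\n", sep = "")
  invisible(x)
}

pair_keys <- function(set) {
  paste(set$pairs$disease, set$pairs$cell_type, sep = "\r")
}

check_same_universe <- function(a, b) {
  if (!identical(a$diseases, b$diseases) ||
      !identical(a$cell_types, b$cell_types)) {
    stop("association sets are defined over different universes")
  }
}

#' Significance of the overlap between two association sets
#'
#' One-tailed Fisher's exact test on the 2x2 table (shared pairs, pairs
#' only in `a`, pairs only in `b`, remaining universe), asking whether the
#' two sets share more associations than expected by chance.
#'
#' @param a,b `association_set` objects over the same universe.
#' @param log_p Return the natural log of the P value instead.
#' @return The one-tailed P value (or its log).
#' @export
overlap_significance <- function(a, b, log_p = FALSE) {
  check_same_universe(a, b)
  universe <- length(a$diseases) * length(a$cell_types)
  n_both <- length(intersect(pair_keys(a), pair_keys(b)))
  n_a <- nrow(a$pairs) - n_both
  n_b <- nrow(b$pairs) - n_both
  fisher_enrichment_test(n_both, n_a, n_b, universe - n_both - n_a - n_b,
                         log_p = log_p)
}

#' Precision, recall and F1 of predicted associations
#'
#' Treats `truth` as the reference set of true (disease, cell type) pairs.
#' An empty prediction has precision 0; F1 is 0 when precision and recall
#' are both 0.
#'
#' @param predicted,truth `association_set` objects over the same universe.
#' @return A one-row tibble: `precision`, `recall`, `f1`, `n_predicted`,
#'   `n_truth`, `n_overlap`.
#' @export
precision_recall_f1 <- function(predicted, truth) {
  check_same_universe(predicted, truth)
  n_overlap <- length(intersect(pair_keys(predicted), pair_keys(truth)))
  n_pred <- nrow(predicted$pairs)
  n_truth <- nrow(truth$pairs)
  precision <- if (n_pred == 0L) 0 else n_overlap / n_pred
  recall <- if (n_truth == 0L) 0 else n_overlap / n_truth
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 n_predicted = n_pred, n_truth = n_truth,
                 n_overlap = n_overlap)
}

#' Bin diseases by number of associated genes
#'
#' Diseases are sorted in descending order of gene-set size and filled
#' greedily into bins: a new bin opens once the current bin holds at least
#' `min_bin` diseases, except that diseases tied on set size always stay in
#' the same bin as their peers.
#'
#' @param sets Named list of gene sets (character vectors).
#' @param min_bin Minimum bin size (default 20).
#' @return Tibble with columns `disease`, `n_genes`, `bin` (1 = largest
#'   sets).
#' @export
make_disease_bins <- function(sets, min_bin = 20L) {
  if (length(sets) == 0L) {
    return(tibble::tibble(disease = character(0), n_genes = integer(0),
                          bin = integer(0)))
  }
  sizes <- lengths(sets)
  ord <- order(-sizes, names(sets))
  sizes <- sizes[ord]
  diseases <- names(sets)[ord]
  bin <- integer(length(sizes))
  current <- 1L
  count <- 0L
  for (i in seq_along(sizes)) {
    if (count >= min_bin && (i == 1L || sizes[[i]] != sizes[[i - 1L]])) {
      current <- current + 1L
      count <- 0L
    }
    bin[[i]] <- current
    count <- count + 1L
  }
  tibble::tibble(disease = diseases, n_genes = as.integer(sizes), bin = bin)
}

#' Evaluate the GSC test over a parameter grid
#'
#' For each combination of interaction confidence cutoff and restart
#' probability: edges are filtered to `score > cutoff`, the GSC test is run
#' for every gene set, P values are adjusted (global BH), pairs with
#' `q_value < fdr` become the predicted association set, and precision,
#' recall and F1 against `truth` are reported.
#'
#' @param sets Named list of gene sets.
#' @param edges Edge list with a `score` column on the 0-1 scale.
#' @param profiles Gene x cell-type matrix of percentile scores.
#' @param truth `association_set` of reference associations.
#' @param confidence_cutoffs,restart_probs Numeric grids.
#' @param u Number of permutations per test.
#' @param fdr FDR threshold for calling associations (default 0.1).
#' @param seed Optional integer seed (re-derived per grid point).
#' @return Tibble with one row per grid point: `confidence_cutoff`,
#'   `restart_prob`, `precision`, `recall`, `f1`, `n_predicted`.
#' @export
parameter_grid_eval <- function(sets, edges, profiles, truth,
                                confidence_cutoffs = c(0, 0.2, 0.4, 0.6, 0.8),
                                restart_probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                u = 10000L, fdr = 0.1, seed = NULL) {
  if (!"score" %in% colnames(edges)) {
    stop("edges need a 'score' column for confidence filtering")
  }
  grid <- expand.grid(confidence_cutoff = confidence_cutoffs,
                      restart_prob = restart_probs,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cutoff <- grid$confidence_cutoff[[i]]
    rprob <- grid$restart_prob[[i]]
    kept <- edges[edges$score > cutoff, , drop = FALSE]
    point_seed <- if (is.null(seed)) NULL else seed + i
    res <- adjust_fdr(gsc_test(sets, kept, profiles, u = u, r = rprob,
                               seed = point_seed))
    predicted <- association_set(
      res[res$q_value < fdr, c("disease", "cell_type")],
      diseases = truth$diseases, cell_types = truth$cell_types
    )
    prf <- precision_recall_f1(predicted, truth)
    tibble::tibble(confidence_cutoff = cutoff, restart_prob = rprob,
                   precision = prf$precision, recall = prf$recall,
                   f1 = prf$f1, n_predicted = prf$n_predicted)
  })
  rows
}
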