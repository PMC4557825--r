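#' Build a cell-type-based disease network
#'
#' Diseases with no cell-type association passing the FDR threshold are
#' removed. Each remaining disease is characterized by its `-log10(q)`
#' profile over cell types; Pearson correlations are computed between all
#' disease pairs and every disease contributes an undirected edge to the
#' `k` diseases with which it correlates most strongly (mutual selections
#' merge into a single edge). Correlation ties at rank k are broken by
#' lexicographic disease identifier. Diseases with a zero-variance profile
#' are excluded with a warning (their correlation is undefined).
#'
#' @param table Association table covering every (disease, cell type) pair,
#'   with a `q_value` column (added by global BH adjustment if absent).
#' @param fdr FDR threshold (default 0.1); a disease needs at least one
#'   `q_value < fdr` to stay.
#' @param k Number of strongest correlates each disease connects to
#'   (default 4).
#' @return A `diseasome` object: `vertices` (tibble with `disease`) and
#'   `edges` (tibble with `from`, `to`, `correlation`).
#' @export
build_diseasome <- function(table, fdr = 0.1, k = 4L) {
  table <- tibble::as_tibble(table)
  if (!"q_value" %in% colnames(table)) table <- adjust_fdr(table)
  wide <- tidyr::pivot_wider(table[c("disease", "cell_type", "q_value")],
                             names_from = "cell_type",
                             values_from = "q_value")
  mat <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(mat) <- wide$disease
  if (anyNA(mat)) {
    stop("association table does not cover every (disease, cell type) pair")
  }
  keep <- rowSums(mat < fdr) > 0
  mat <- mat[keep, , drop = FALSE]
  profile <- -log10(mat)
  flat <- apply(profile, 1, stats::sd) == 0
  if (any(flat)) {
    warning(sum(flat), " disease(s) excluded: zero-variance q profile (",
            paste(utils::head(rownames(profile)[flat], 5), collapse = ", "),
            ")")
    profile <- profile[!flat, , drop = FALSE]
  }
  diseases <- sort(rownames(profile))
  if (length(diseases) < k + 1L) {
    stop("need more than k = ", k, " diseases after FDR filtering; have ",
         length(diseases))
  }
  profile <- profile[diseases, , drop = FALSE]
  cors <- stats::cor(t(profile))

  edge_list <- list()
  for (d in diseases) {
    others <- setdiff(diseases, d)
    # descending correlation, lexicographic tie-break (others is sorted)
    chosen <- others[order(-cors[d, others])][seq_len(k)]
    edge_list[[d]] <- tibble::tibble(
      from = pmin(d, chosen), to = pmax(d, chosen),
      correlation = cors[cbind(d, chosen)]
    )
  }
  edges <- dplyr::distinct(dplyr::bind_rows(edge_list))
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  structure(
    list(vertices = tibble::tibble(disease = diseases), edges = edges,
         k = k, fdr = fdr),
    class = "diseasome"
  )
}

#' @export
print.diseasome <- function(x, ...) {
  cat("<diseasome> ", nrow(x$vertices), " diseases, ", nrow(x$edges),
      " edges (k = ", x$k, ", FDR ", x$fdr, ")\n", sep = "")
  invisible(x)
}
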