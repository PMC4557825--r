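#' Tidy an association test result
#'
#' @param x An `association_test` tibble from [gsc_test()] or [gso_test()].
#' @param ... Unused.
#' @return A plain tibble with one row per (disease, cell type) and a
#'   `method` column.
#' @export
tidy.association_test <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x))
  out$method <- attr(x, "method") %||% NA_character_
  out
}

#' Summarize an association test result
#'
#' @param x An `association_test` tibble.
#' @param fdr FDR threshold used to count significant associations
#'   (default 0.1, on globally BH-adjusted P values).
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n_diseases`, `n_cell_types`, `u`,
#'   `min_p`, `n_significant`.
#' @export
glance.association_test <- function(x, fdr = 0.1, ...) {
  q <- if ("q_value" %in% colnames(x)) x$q_value else bh_adjust(x$p_value)
  tibble::tibble(
    method = attr(x, "method") %||% NA_character_,
    n_diseases = length(unique(x$disease)),
    n_cell_types = length(unique(x$cell_type)),
    u = attr(x, "u") %||% NA_integer_,
    min_p = min(x$p_value),
    n_significant = sum(q < fdr)
  )
}

#' Tidy a diseasome
#'
#' @param x A `diseasome` object.
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`, `correlation`).
#' @export
tidy.diseasome <- function(x, ...) {
  x$edges
}

#' Summarize a diseasome
#'
#' @param x A `diseasome` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_diseases`, `n_edges`, `min_degree`,
#'   `mean_correlation`, `k`, `fdr`.
#' @export
glance.diseasome <- function(x, ...) {
  degree <- table(c(x$edges$from, x$edges$to))
  tibble::tibble(
    n_diseases = nrow(x$vertices),
    n_edges = nrow(x$edges),
    min_degree = as.integer(min(degree)),
    mean_correlation = mean(x$edges$correlation),
    k = x$k,
    fdr = x$fdr
  )
}
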