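#' Read a gene-by-sample expression matrix from TSV
#'
#' The first column must contain gene identifiers and the remaining columns
#' one sample each; a header row is required. Values are raw counts or
#' tags-per-million and must be nonnegative.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix (genes x samples) with gene identifiers as row
#'   names and sample identifiers as column names.
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    stop("no data rows in expression matrix file '", path, "'")
  }
  genes <- as.character(raw[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L) {
    stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  samples <- colnames(raw)[-1L]
  dup_s <- samples[duplicated(samples)]
  if (length(dup_s) > 0L) {
    stop("duplicate sample identifier(s): ",
         paste(unique(dup_s), collapse = ", "))
  }
  values <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop("negative expression value for gene '", genes[neg[1L, 1L]],
         "' in sample '", samples[neg[1L, 2L]], "'")
  }
  rownames(values) <- genes
  values
}

#' Write an expression matrix to TSV
#'
#' @param matrix Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @param id_column Name for the gene-identifier column.
#' @export
write_expression_matrix <- function(matrix, path, id_column = "gene_id") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample grouping table
#'
#' Expects a TSV with columns `sample_id`, `sub_facet` and `facet`, the
#' two-level hierarchy used for sample quality control and combining.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with columns `sample_id`, `sub_facet`, `facet`.
#' @export
read_sample_grouping <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "sub_facet", "facet")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0L) {
    stop("grouping table misses column(s): ", paste(missing, collapse = ", "))
  }
  grouping <- tibble::as_tibble(df[required])
  validate_grouping(grouping)
  grouping
}

validate_grouping <- function(grouping) {
  split_map <- unique(grouping[c("sub_facet", "facet")])
  bad <- split_map$sub_facet[duplicated(split_map$sub_facet)]
  if (length(bad) > 0L) {
    stop("sub-facet(s) mapped to more than one facet: ",
         paste(unique(bad), collapse = ", "))
  }
  if (anyDuplicated(grouping$sample_id)) {
    stop("duplicate sample_id in grouping table")
  }
  invisible(grouping)
}

#' Read a STRING-style protein links file
#'
#' Parses the whitespace-delimited STRING protein-links dialect (header
#' line, `protein1`, `protein2`, then one column per evidence channel on the
#' 0--1000 integer scale). Channel scores are rescaled to 0--1 on load and a
#' record is kept only when the selected channel score strictly exceeds
#' `threshold`. Orientation is collapsed: a--b and b--a become a single
#' record keeping, per channel, the maximum of the two scores. Self-links
#' are dropped.
#'
#' @param path Path to a protein-links file.
#' @param score_channel Name of the evidence channel used for filtering
#'   (e.g. `"experimental"`).
#' @param threshold Confidence threshold on the 0--1 scale; records must
#'   exceed it strictly.
#' @param mapping Optional two-column data frame (or TSV path) mapping
#'   protein identifiers to gene identifiers; records with an unmapped
#'   endpoint are dropped and the count is reported via `message()`.
#' @return A tibble with columns `protein_a`, `protein_b`, one column per
#'   channel (0--1 scale), and `score` (the selected channel).
#' @export
read_string_links <- function(path, score_channel = "experimental",
                              threshold = 0.8, mapping = NULL) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) {
    stop("protein links file must have two identifier columns and at least ",
         "one score channel")
  }
  channels <- colnames(df)[-(1:2)]
  if (!score_channel %in% channels) {
    stop("unknown score channel '", score_channel, "'; available: ",
         paste(channels, collapse = ", "))
  }
  colnames(df)[1:2] <- c("protein_a", "protein_b")
  for (ch in channels) df[[ch]] <- df[[ch]] / 1000

  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1L) {
      mapping <- utils::read.delim(mapping, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
    }
    map <- stats::setNames(as.character(mapping[[2L]]),
                           as.character(mapping[[1L]]))
    a <- map[df$protein_a]
    b <- map[df$protein_b]
    unmapped <- is.na(a) | is.na(b)
    if (any(unmapped)) {
      message(sum(unmapped), " record(s) dropped: unmapped protein identifier")
    }
    df <- df[!unmapped, , drop = FALSE]
    df$protein_a <- a[!unmapped]
    df$protein_b <- b[!unmapped]
  }

  df <- df[df$protein_a != df$protein_b, , drop = FALSE]
  # canonical orientation, then per-channel maximum over duplicate records
  lo <- pmin(df$protein_a, df$protein_b)
  hi <- pmax(df$protein_a, df$protein_b)
  df$protein_a <- lo
  df$protein_b <- hi
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(df), .data$protein_a, .data$protein_b),
    dplyr::across(dplyr::all_of(channels), max),
    .groups = "drop"
  )
  out$score <- out[[score_channel]]
  out <- out[out$score > threshold, , drop = FALSE]
  dplyr::arrange(out, .data$protein_a, .data$protein_b)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then one member per field. Duplicate members within a line
#' are collapsed with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene identifiers; set
#'   descriptions are kept in the `"descriptions"` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no gene sets in '", path, "'")
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop("GMT line ", i, ": fewer than 3 fields (need name, description ",
           "and at least one member)")
    }
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning("GMT line ", i, " ('", fields[[1L]],
              "'): duplicate members collapsed")
      members <- unique(members)
    }
    nms[[i]] <- fields[[1L]]
    descs[[i]] <- fields[[2L]]
    sets[[i]] <- members
  }
  if (anyDuplicated(nms)) {
    stop("duplicate gene set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(descs, nms)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- rep("na", length(sets))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write an association table to TSV
#'
#' Rows are ordered by disease then cell type (lexicographic) so output is
#' deterministic. If `q_value` is missing it is added by global
#' Benjamini-Hochberg adjustment of `p_value`.
#'
#' @param results Association table (e.g. from [gsc_test()]).
#' @param path Output path.
#' @export
write_association_table <- function(results, path) {
  results <- tibble::as_tibble(results)
  required <- c("disease", "cell_type", "statistic", "p_value")
  missing <- setdiff(required, colnames(results))
  if (length(missing) > 0L) {
    stop("association table misses column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"q_value" %in% colnames(results)) {
    results <- adjust_fdr(results)
  }
  out <- dplyr::arrange(
    results[c("disease", "cell_type", "statistic", "p_value", "q_value")],
    .data$disease, .data$cell_type
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association table written by [write_association_table()]
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `disease`, `cell_type`, `statistic`,
#'   `p_value`, `q_value`.
#' @export
read_association_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Export a network to GraphML or a TSV edge list
#'
#' Vertex identifiers and edge attributes (weights for interactomes,
#' correlations for diseasomes) are preserved. Isolated vertices appear in
#' GraphML output but, by format semantics, not in an edge list.
#'
#' @param graph A `cell_interactome` or `diseasome` object, or an igraph.
#' @param path Output path.
#' @param format `"graphml"` or `"tsv_edgelist"`.
#' @export
write_graph <- function(graph, path, format = c("graphml", "tsv_edgelist")) {
  format <- match.arg(format)
  g <- to_igraph(graph)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

to_igraph <- function(graph) {
  if (inherits(graph, "igraph")) return(graph)
  if (inherits(graph, "cell_interactome")) {
    el <- data.frame(
      from = graph$vertices[graph$edges[, 1L]],
      to = graph$vertices[graph$edges[, 2L]],
      weight = graph$weight,
      stringsAsFactors = FALSE
    )
    return(igraph::graph_from_data_frame(el, directed = FALSE,
                                         vertices = graph$vertices))
  }
  if (inherits(graph, "diseasome")) {
    el <- as.data.frame(graph$edges)
    colnames(el)[colnames(el) == "correlation"] <- "weight"
    return(igraph::graph_from_data_frame(el, directed = FALSE,
                                         vertices = graph$vertices$disease))
  }
  stop("cannot export object of class ", paste(class(graph), collapse = "/"))
}

#' Read a disease/cell-type literature co-occurrence table
#'
#' Expects a TSV with columns `disease`, `cell_type`, `n_both`,
#' `n_disease_only`, `n_cell_only`, `corpus_size` (article counts).
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with the columns above.
#' @export
read_cooccurrence_table <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, header = TRUE, sep = "\t",
                                            stringsAsFactors = FALSE))
  required <- c("disease", "cell_type", "n_both", "n_disease_only",
                "n_cell_only", "corpus_size")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0L) {
    stop("co-occurrence table misses column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}
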