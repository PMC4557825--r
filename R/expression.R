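#' Aggregate CAGE peak counts to gene-level counts
#'
#' Each peak is assigned to a gene when the distance between the peak
#' midpoint and some transcript 5' end annotated for that gene is at most
#' `window` base pairs. Counts of all peaks assigned to a gene are summed.
#' When several genes' 5' ends fall within the window, the peak goes to the
#' nearest one; exact ties go to all tied genes by default (`multi =
#' "all"`), with the count contributed to each.
#'
#' Coordinates follow the BED convention: 0-based, half-open intervals for
#' peaks; `position` in `tss_annotation` is the 0-based coordinate of the
#' transcript 5' end.
#'
#' @param peak_counts Numeric matrix of peak x sample counts with peak
#'   identifiers as row names.
#' @param peak_positions Data frame with columns `peak_id`, `chrom`,
#'   `start`, `end`.
#' @param tss_annotation Data frame with columns `chrom`, `position`,
#'   `gene_id`.
#' @param window Maximum distance in bp (default 500).
#' @param multi How to resolve exact distance ties between genes: assign to
#'   `"all"` tied genes or `"first"` (lexicographically smallest gene id).
#' @return A gene x sample count matrix; peaks with no gene within the
#'   window are dropped.
#' @export
aggregate_peaks_to_genes <- function(peak_counts, peak_positions,
                                     tss_annotation, window = 500,
                                     multi = c("all", "first")) {
  multi <- match.arg(multi)
  if (window < 0) stop("window must be >= 0")
  stopifnot(all(c("peak_id", "chrom", "start", "end") %in%
                  colnames(peak_positions)),
            all(c("chrom", "position", "gene_id") %in%
                  colnames(tss_annotation)))
  pos <- peak_positions[match(rownames(peak_counts), peak_positions$peak_id),
                        , drop = FALSE]
  if (anyNA(pos$peak_id)) stop("peak(s) in count matrix lack coordinates")
  mid <- (pos$start + pos$end) / 2

  assign_gene <- vector("list", nrow(pos))
  n_multi <- 0L
  for (i in seq_len(nrow(pos))) {
    on_chrom <- tss_annotation$chrom == pos$chrom[[i]]
    if (!any(on_chrom)) next
    d <- abs(tss_annotation$position[on_chrom] - mid[[i]])
    ok <- d <= window
    if (!any(ok)) next
    genes <- tss_annotation$gene_id[on_chrom][ok]
    dmin <- min(d[ok])
    nearest <- sort(unique(genes[d[ok] == dmin]))
    if (length(nearest) > 1L) {
      n_multi <- n_multi + 1L
      if (multi == "first") nearest <- nearest[[1L]]
    }
    assign_gene[[i]] <- nearest
  }
  if (n_multi > 0L) {
    message(n_multi, " peak(s) equidistant from multiple genes (multi = '",
            multi, "')")
  }
  keep <- lengths(assign_gene) > 0L
  if (!any(keep)) stop("no peak could be assigned to a gene")
  rows <- rep(which(keep), lengths(assign_gene[keep]))
  genes <- unlist(assign_gene[keep], use.names = FALSE)
  out <- rowsum(peak_counts[rows, , drop = FALSE], group = genes)
  out[sort(rownames(out)), , drop = FALSE]
}

#' Relative log expression normalization to tags per million
#'
#' Per-sample size factors are the median, over genes with a nonzero
#' geometric mean across samples, of the ratio of the gene's count to its
#' geometric mean. Counts are divided by the size factor and each sample is
#' then rescaled to sum to one million, giving gene-wise tags per million.
#'
#' @param matrix Nonnegative gene x sample count matrix with at least two
#'   samples.
#' @return Normalized matrix of the same shape, each column summing to 1e6.
#' @export
rle_normalize <- function(matrix) {
  if (ncol(matrix) < 2L) stop("RLE normalization needs at least 2 samples")
  if (any(matrix < 0)) stop("counts must be nonnegative")
  zero_samples <- colSums(matrix) == 0
  if (any(zero_samples)) {
    stop("all genes zero in sample '",
         colnames(matrix)[which(zero_samples)[1L]], "'")
  }
  positive <- rowSums(matrix > 0) == ncol(matrix)
  if (!any(positive)) {
    stop("no gene has a nonzero geometric mean across samples")
  }
  geomean <- exp(rowMeans(log(matrix[positive, , drop = FALSE])))
  size_factors <- apply(matrix[positive, , drop = FALSE], 2, function(col) {
    stats::median(col / geomean)
  })
  scaled <- sweep(matrix, 2, size_factors, "/")
  sweep(scaled, 2, colSums(scaled), "/") * 1e6
}

#' Relative expression across cell types
#'
#' For gene i in cell type l, the relative expression is
#' `e'[i, l] = k * e[i, l] / sum_j e[i, j]` where `k` is the number of cell
#' types, so the mean over cell types is exactly 1 for any gene with
#' nonzero total expression. All-zero genes get 0 everywhere.
#'
#' @param matrix Nonnegative gene x cell-type matrix (one column per cell
#'   type, `k >= 2`).
#' @return Matrix of relative expression values, same shape.
#' @export
relative_expression <- function(matrix) {
  k <- ncol(matrix)
  if (k < 2L) stop("relative expression needs k >= 2 cell types")
  totals <- rowSums(matrix)
  out <- k * matrix / ifelse(totals == 0, 1, totals)
  out[totals == 0, ] <- 0
  out
}

#' Percentile-normalize relative expression per cell type
#'
#' Within each cell type, genes are ranked in ascending order of relative
#' expression and the rank is rescaled to `(rank - 1) / (n - 1)`, giving
#' scores distributed uniformly on `[0, 1]`: 1 marks the most overexpressed
#' gene of that cell type, 0 the most underexpressed. Ties receive the
#' average of their ranks before rescaling.
#'
#' @param rel Gene x cell-type matrix of relative expression values
#'   (at least two genes).
#' @return Matrix of percentile scores in `[0, 1]`, same shape.
#' @export
percentile_scores <- function(rel) {
  rel <- as.matrix(rel)
  n <- nrow(rel)
  if (n < 2L) stop("percentile scores undefined for a single gene")
  apply(rel, 2, function(col) {
    (rank(col, ties.method = "average") - 1) / (n - 1)
  })
}

#' Jensen-Shannon distance between two distributions
#'
#' The square root of the Jensen-Shannon divergence with base-2 logarithms,
#' a symmetric, bounded (`[0, 1]`) measure of dissimilarity between two
#' probability vectors. Inputs must sum to 1 within 1e-6 and are
#' renormalized.
#'
#' @param p,q Nonnegative numeric vectors of equal length.
#' @return The distance, a number in `[0, 1]`.
#' @export
jensen_shannon_distance <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (any(p < 0) || any(q < 0)) stop("p and q must be nonnegative")
  sp <- sum(p); sq <- sum(q)
  if (sp == 0 || sq == 0) stop("zero-sum vector")
  if (abs(sp - 1) > 1e-6 || abs(sq - 1) > 1e-6) {
    stop("inputs must sum to 1 (within 1e-6)")
  }
  p <- p / sp
  q <- q / sq
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * (log2(a[nz]) - log2(b[nz])))
  }
  div <- (kl(p, m) + kl(q, m)) / 2
  sqrt(max(div, 0))
}

pairwise_jsd <- function(matrix) {
  probs <- sweep(matrix, 2, colSums(matrix), "/")
  n <- ncol(probs)
  d <- matrix(0, n, n, dimnames = list(colnames(probs), colnames(probs)))
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- jensen_shannon_distance(probs[, i], probs[, j])
      }
    }
  }
  d
}

#' Quality-control filter on replicate samples
#'
#' Within each sub-facet: sub-facets with a single sample are removed;
#' otherwise samples (normalized to sum 1) are clustered by complete-linkage
#' hierarchical clustering on pairwise Jensen-Shannon distances, the tree is
#' cut at `cut_height`, and only samples in the largest cluster are kept.
#' If no cluster holds more than one sample, the whole sub-facet is removed.
#'
#' @param matrix Gene x sample expression matrix.
#' @param grouping Tibble with `sample_id`, `sub_facet`, `facet` covering
#'   every sample in the matrix.
#' @param cut_height Tree cut height on the JSD scale (default 0.35).
#' @return The matrix restricted to the retained samples (original values).
#' @export
qc_filter_samples <- function(matrix, grouping, cut_height = 0.35) {
  validate_grouping(grouping)
  samples <- colnames(matrix)
  missing <- setdiff(samples, grouping$sample_id)
  if (length(missing) > 0L) {
    stop("sample(s) without grouping: ", paste(missing, collapse = ", "))
  }
  sub_of <- stats::setNames(grouping$sub_facet, grouping$sample_id)
  kept <- character(0)
  for (sf in unique(sub_of[samples])) {
    members <- samples[sub_of[samples] == sf]
    if (length(members) < 2L) next  # singleton sub-facets removed
    d <- pairwise_jsd(matrix[, members, drop = FALSE])
    tree <- stats::hclust(stats::as.dist(d), method = "complete")
    clusters <- stats::cutree(tree, h = cut_height)
    sizes <- table(clusters)
    if (max(sizes) < 2L) next  # no cluster with >1 sample: drop sub-facet
    biggest <- names(sizes)[sizes == max(sizes)]
    if (length(biggest) > 1L) {
      # deterministic tie-break: cluster containing the alphabetically
      # first sample among the tied clusters
      first_in <- vapply(biggest, function(cl) {
        min(members[clusters == as.integer(cl)])
      }, character(1L))
      biggest <- biggest[order(first_in)][[1L]]
    }
    kept <- c(kept, members[clusters == as.integer(biggest[[1L]])])
  }
  matrix[, samples[samples %in% kept], drop = FALSE]
}

#' Combine replicate samples into one profile per cell type
#'
#' Within each facet the mean pairwise Jensen-Shannon distance between its
#' samples decides the grouping level: above `split_threshold` the facet is
#' heterogeneous and one profile is produced per sub-facet; otherwise a
#' single profile is produced for the facet. Profiles are arithmetic means
#' of the per-sample values (mean tags per million). A facet with a single
#' sample is passed through under the facet name.
#'
#' @param matrix Gene x sample expression matrix (after QC).
#' @param grouping Tibble with `sample_id`, `sub_facet`, `facet`.
#' @param split_threshold Mean-JSD threshold (default 0.25).
#' @return Gene x cell-type matrix, one column per derived cell type.
#' @export
combine_samples <- function(matrix, grouping, split_threshold = 0.25) {
  validate_grouping(grouping)
  samples <- colnames(matrix)
  missing <- setdiff(samples, grouping$sample_id)
  if (length(missing) > 0L) {
    stop("sample(s) without grouping: ", paste(missing, collapse = ", "))
  }
  g <- grouping[match(samples, grouping$sample_id), ]
  cols <- list()
  for (fac in unique(g$facet)) {
    members <- samples[g$facet == fac]
    if (length(members) == 1L) {
      cols[[fac]] <- matrix[, members]
      next
    }
    d <- pairwise_jsd(matrix[, members, drop = FALSE])
    mean_jsd <- mean(d[upper.tri(d)])
    if (mean_jsd > split_threshold) {
      subs <- g$sub_facet[match(members, g$sample_id)]
      for (sf in unique(subs)) {
        cols[[sf]] <- rowMeans(matrix[, members[subs == sf], drop = FALSE])
      }
    } else {
      cols[[fac]] <- rowMeans(matrix[, members, drop = FALSE])
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(matrix)
  out
}

#' Draw one permuted expression profile
#'
#' Emulates the permutation scheme of the overexpression and compactness
#' tests: a cell type is drawn uniformly at random and the gene-to-score
#' assignment of that column is shuffled uniformly, so the permuted column
#' carries exactly the score multiset of one observed cell type
#' (`method = "column"`, the default). The alternative reading
#' (`method = "per_gene"`) resamples, independently for every gene, a score
#' from a uniformly drawn (gene, cell type) entry.
#'
#' @param profiles Gene x cell-type matrix of percentile scores.
#' @param seed Optional integer seed for reproducibility.
#' @param method Permutation scheme; see Details.
#' @return One-column matrix of permuted scores (column `"permuted"`).
#' @export
permute_profiles <- function(profiles, seed = NULL,
                             method = c("column", "per_gene")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(profiles)
  if (method == "column") {
    l <- sample.int(ncol(profiles), 1L)
    scores <- profiles[sample.int(n), l]
  } else {
    scores <- profiles[cbind(sample.int(n, n, replace = TRUE),
                             sample.int(ncol(profiles), n, replace = TRUE))]
  }
  out <- matrix(scores, ncol = 1L,
                dimnames = list(rownames(profiles), "permuted"))
  out
}

#' Diagnostic counts of extreme relative expression per cell type
#'
#' Counts, per cell type, genes whose relative expression exceeds the global
#' top-0.1% value. A cell type with an outlying count (relative to the
#' others) has a skewed profile that the percentile normalization cannot
#' fully absorb; users may choose to drop such columns before building
#' interactomes.
#'
#' @param rel Gene x cell-type matrix of relative expression values.
#' @return Tibble with columns `cell_type`, `n_extreme`, `threshold`.
#' @export
expression_diagnostics <- function(rel) {
  threshold <- stats::quantile(rel, 0.999, names = FALSE)
  tibble::tibble(
    cell_type = colnames(rel),
    n_extreme = unname(apply(rel, 2, function(col) sum(col > threshold))),
    threshold = threshold
  )
}
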