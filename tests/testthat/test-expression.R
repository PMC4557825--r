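test_that("peak aggregation follows the 500 bp window and sums counts", {
  counts <- matrix(c(3, 7, 5, 2,
                     1, 1, 1, 1), ncol = 2,
                   dimnames = list(c("p1", "p2", "p3", "p4"),
                                   c("s1", "s2")))
  peaks <- data.frame(peak_id = c("p1", "p2", "p3", "p4"),
                      chrom = "chr1",
                      start = c(990, 1400, 2512, 9000),
                      end = c(1010, 1420, 2512, 9002))
  # midpoints: 1000, 1410, 2512, 9001
  tss <- data.frame(chrom = "chr1", position = c(1000, 2011),
                    gene_id = c("geneA", "geneB"))
  out <- aggregate_peaks_to_genes(counts, peaks, tss, window = 500)
  # p1 at distance 0 -> geneA; p2 at 410 -> geneA; p3 at 501 -> dropped;
  # p4 far away -> dropped; geneA sums 3 + 7
  expect_identical(rownames(out), "geneA")
  expect_equal(out["geneA", ], c(s1 = 10, s2 = 2))
})

test_that("equidistant peaks go to both genes by default", {
  counts <- matrix(4, 1, 1, dimnames = list("p1", "s1"))
  peaks <- data.frame(peak_id = "p1", chrom = "chr1",
                      start = 1000, end = 1000)
  tss <- data.frame(chrom = "chr1", position = c(900, 1100),
                    gene_id = c("geneA", "geneB"))
  expect_message(
    both <- aggregate_peaks_to_genes(counts, peaks, tss, window = 500),
    "equidistant"
  )
  expect_equal(both[, "s1"], c(geneA = 4, geneB = 4))
  expect_message(
    first <- aggregate_peaks_to_genes(counts, peaks, tss, window = 500,
                                      multi = "first")
  )
  expect_identical(rownames(first), "geneA")
})

test_that("RLE normalization recovers size factors and scales to TPM", {
  base <- matrix(c(10, 20, 30, 40), ncol = 1)
  mat <- cbind(s1 = base[, 1], s2 = base[, 1])
  rownames(mat) <- paste0("g", 1:4)
  norm <- rle_normalize(mat)
  expect_equal(norm[, "s1"], norm[, "s2"])
  expect_equal(colSums(norm), c(s1 = 1e6, s2 = 1e6))

  # doubling a sample: median ratio 2, normalized matrices identical
  mat2 <- cbind(s1 = base[, 1], s2 = 2 * base[, 1])
  rownames(mat2) <- paste0("g", 1:4)
  norm2 <- rle_normalize(mat2)
  expect_equal(norm2[, "s1"], norm2[, "s2"])

  single <- matrix(c(5, 11), 1, 2,
                   dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(rle_normalize(single)[1, ]), c(1e6, 1e6))

  zero <- cbind(s1 = c(1, 2), s2 = c(0, 0))
  rownames(zero) <- c("g1", "g2")
  expect_error(rle_normalize(zero), "s2")
})

test_that("RLE size factors agree with the edgeR implementation", {
  skip_if_not_installed("edgeR")
  set.seed(81)
  mat <- matrix(rnbinom(600, mu = 40, size = 3) + 1L, 100, 6,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  mat[, 3] <- mat[, 3] * 3L
  ours <- apply(mat, 2, function(col) {
    stats::median(col / exp(rowMeans(log(mat))))
  })
  theirs <- edgeR::calcNormFactors(mat, method = "RLE") * colSums(mat)
  # both are defined up to a common rescaling
  expect_equal(unname(ours / exp(mean(log(ours)))),
               unname(theirs / exp(mean(log(theirs)))), tolerance = 1e-10)
})

test_that("relative expression matches its defining formula", {
  mat <- rbind(flat = c(7, 7, 7, 7),
               spread = c(10, 0, 0, 30),
               silent = c(0, 0, 0, 0))
  colnames(mat) <- paste0("ct", 1:4)
  rel <- relative_expression(mat)
  expect_equal(unname(rel["flat", ]), rep(1, 4))
  expect_equal(unname(rel["spread", ]), c(1, 0, 0, 3))
  expect_equal(unname(rel["silent", ]), rep(0, 4))
  # mean across cell types is exactly 1 for expressed genes
  expect_equal(unname(rowMeans(rel)[c("flat", "spread")]), c(1, 1))
  expect_error(relative_expression(mat[, 1, drop = FALSE]), "k >= 2")
})

test_that("percentile scores are uniform ranks with average ties", {
  col <- matrix(c(0.2, 3.0, 1.0, 0.5, 2.0), ncol = 1,
                dimnames = list(paste0("g", 1:5), "ct1"))
  expect_equal(unname(percentile_scores(col)[, 1]),
               c(0, 1, 0.5, 0.25, 0.75))

  tied <- matrix(c(1, 1, 5), ncol = 1,
                 dimnames = list(paste0("g", 1:3), "ct1"))
  expect_equal(unname(percentile_scores(tied)[, 1]), c(0.25, 0.25, 1))

  set.seed(4)
  rel <- matrix(runif(200), 50, 4,
                dimnames = list(paste0("g", 1:50), paste0("ct", 1:4)))
  sc <- percentile_scores(rel)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(unname(colMeans(sc)), rep(0.5, 4))
  expect_equal(unname(apply(sc, 2, min)), rep(0, 4))
  expect_equal(unname(apply(sc, 2, max)), rep(1, 4))
  # every column is the exact uniform grid when values are distinct
  grid <- (0:49) / 49
  for (l in 1:4) expect_equal(unname(sort(sc[, l])), grid)

  expect_error(percentile_scores(matrix(1, 1, 1)), "single gene")
})

test_that("Jensen-Shannon distance is a bounded metric", {
  p <- c(0.25, 0.25, 0.5)
  expect_equal(jensen_shannon_distance(p, p), 0)
  expect_equal(jensen_shannon_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(jensen_shannon_distance(c(1, 0), c(0.5, 0.5)),
               sqrt(0.311278), tolerance = 1e-5)
  q <- c(0.6, 0.3, 0.1)
  expect_equal(jensen_shannon_distance(p, q),
               jensen_shannon_distance(q, p))
  # triangle inequality spot-check
  r <- c(0.1, 0.1, 0.8)
  expect_lte(jensen_shannon_distance(p, r),
             jensen_shannon_distance(p, q) + jensen_shannon_distance(q, r))
  expect_error(jensen_shannon_distance(c(0, 0), c(1, 0)), "zero-sum")
  expect_error(jensen_shannon_distance(c(0.7, 0.1), c(0.5, 0.5)), "sum to 1")
})

test_that("sample QC keeps the largest coherent cluster per sub-facet", {
  mat <- cbind(a1 = c(50, 50, 0), a2 = c(50, 50, 0), a3 = c(0, 10, 90),
               b1 = c(30, 30, 40))
  rownames(mat) <- paste0("g", 1:3)
  grouping <- tibble::tibble(
    sample_id = c("a1", "a2", "a3", "b1"),
    sub_facet = c("subA", "subA", "subA", "subB"),
    facet = c("facA", "facA", "facA", "facB")
  )
  kept <- qc_filter_samples(mat, grouping)
  # a1, a2 identical (JSD 0); a3 an outlier; subB is a singleton
  expect_identical(colnames(kept), c("a1", "a2"))
  expect_identical(kept, mat[, c("a1", "a2")])

  # two identical samples alone survive
  two <- mat[, c("a1", "a2")]
  expect_identical(colnames(qc_filter_samples(two, grouping)),
                   c("a1", "a2"))

  # mutually distant samples: no cluster of size > 1, all removed
  far <- cbind(a1 = c(100, 0, 0), a2 = c(0, 100, 0), a3 = c(0, 0, 100))
  rownames(far) <- paste0("g", 1:3)
  expect_identical(ncol(qc_filter_samples(far, grouping)), 0L)

  expect_error(qc_filter_samples(cbind(mat, zz = c(1, 1, 1)), grouping),
               "without grouping")
})

test_that("sample combining splits heterogeneous facets by sub-facet", {
  grouping <- tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2", "c1"),
    sub_facet = c("subA1", "subA2", "subB", "subB", "subC"),
    facet = c("facA", "facA", "facB", "facB", "facC")
  )
  mat <- cbind(a1 = c(96, 2, 2), a2 = c(2, 2, 96),   # very dissimilar
               b1 = c(2, 4, 6), b2 = c(4, 8, 12),    # proportional: JSD 0
               c1 = c(5, 5, 5))
  rownames(mat) <- paste0("g", 1:3)
  out <- combine_samples(mat, grouping)
  expect_setequal(colnames(out), c("subA1", "subA2", "facB", "facC"))
  # facA mean JSD > 0.25: split by sub-facet
  expect_equal(out[, "subA1"], mat[, "a1"])
  # facB mean JSD 0: combined as the arithmetic mean
  expect_equal(unname(out[, "facB"]), c(3, 6, 9))
  # single-sample facet passes through under the facet name
  expect_equal(unname(out[, "facC"]), c(5, 5, 5))
})

test_that("profile permutation preserves the score multiset and seed", {
  set.seed(10)
  profiles <- percentile_scores(
    matrix(runif(60), 20, 3,
           dimnames = list(paste0("g", 1:20), paste0("ct", 1:3)))
  )
  p1 <- permute_profiles(profiles, seed = 99)
  p2 <- permute_profiles(profiles, seed = 99)
  expect_identical(p1, p2)
  expect_equal(unname(sort(p1[, 1])), unname(sort(profiles[, 1])))

  # two genes, one cell type: each gene receives each score ~50% of draws
  two <- matrix(c(0, 1), 2, 1, dimnames = list(c("g1", "g2"), "ct1"))
  set.seed(7)
  hits <- mean(vapply(1:10000,
                      function(i) permute_profiles(two)["g1", 1] == 1,
                      logical(1)))
  expect_lt(abs(hits - 0.5), 3 * sqrt(0.25 / 10000))

  pg <- permute_profiles(profiles, seed = 3, method = "per_gene")
  expect_true(all(pg %in% profiles))
})

test_that("expression diagnostics count extreme relative values", {
  rel <- matrix(1, 2000, 2, dimnames = list(NULL, c("ct1", "ct2")))
  rel[1:3, 2] <- 100
  diag <- expression_diagnostics(rel)
  expect_identical(diag$n_extreme[diag$cell_type == "ct2"], 3L)
  expect_identical(diag$n_extreme[diag$cell_type == "ct1"], 0L)
})
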