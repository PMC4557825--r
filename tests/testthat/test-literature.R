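test_that("Fisher enrichment tail matches hand-computed hypergeometrics", {
  # all 5 disease articles are also cell-type articles in a 10-article
  # corpus: P = 1 / choose(10, 5)
  expect_equal(fisher_enrichment_test(5, 0, 0, 5), 1 / choose(10, 5))
  # zero co-occurrences: the whole tail, P = 1
  expect_equal(fisher_enrichment_test(0, 3, 4, 13), 1)
  expect_error(fisher_enrichment_test(-1, 0, 0, 5), "nonnegative")
})

test_that("the tail is monotone in the co-occurrence count", {
  # fixed margins: disease 6, cell type 8, corpus 50
  p <- vapply(2:6, function(a) {
    fisher_enrichment_test(a, 6 - a, 8 - a, 50 - 14 + a)
  }, numeric(1))
  expect_true(all(diff(p) < 0))
  # independence fixture: observed == expected, no enrichment signal
  expect_gt(fisher_enrichment_test(4, 16, 16, 64), 0.05)
})

test_that("log-space tails agree with direct summation and fisher.test", {
  set.seed(55)
  for (i in 1:25) {
    corpus <- sample(20:200, 1)
    m <- sample.int(corpus %/% 2, 1)
    k <- sample.int(corpus %/% 2, 1)
    a <- sample(0:min(m, k), 1)
    tab <- c(a, m - a, k - a, corpus - m - k + a)
    ours <- fisher_enrichment_test(tab[1], tab[2], tab[3], tab[4])
    expect_equal(ours, exhaustive_fisher_tail(tab[1], tab[2], tab[3],
                                              tab[4]),
                 tolerance = 1e-10)
    expect_equal(ours,
                 stats::fisher.test(matrix(tab, 2), alternative =
                                      "greater")$p.value,
                 tolerance = 1e-8)
  }
})

test_that("co-occurrence tables are tested pairwise with validation", {
  tab <- tibble::tibble(
    disease = c("d1", "d2"), cell_type = c("c1", "c2"),
    n_both = c(5, 0), n_disease_only = c(0, 3), n_cell_only = c(0, 4),
    corpus_size = c(10, 20)
  )
  out <- cooccurrence_fisher(tab)
  expect_equal(out$p_value[1], 1 / choose(10, 5))
  expect_equal(out$log_p, log(out$p_value))

  bad <- tab
  bad$n_both[2] <- 50
  expect_error(cooccurrence_fisher(bad), "d2")
})

test_that("association-set overlap significance behaves at the extremes", {
  diseases <- sprintf("d%03d", 1:196)
  cells <- sprintf("c%02d", 1:73)
  pairs <- tibble::tibble(disease = rep(diseases[1:2], 5),
                          cell_type = cells[1:10])
  a <- association_set(pairs, diseases, cells)
  # identical sets of 10 pairs in a 14,308-pair universe: vanishing P
  expect_lt(overlap_significance(a, a), 1e-20)
  expect_equal(overlap_significance(a, a, log_p = TRUE),
               log(overlap_significance(a, a)), tolerance = 1e-6)

  # disjoint halves of a small universe: no enrichment at all
  u_d <- sprintf("d%d", 1:10)
  u_c <- c("c1", "c2")
  all_pairs <- expand.grid(disease = u_d, cell_type = u_c,
                           stringsAsFactors = FALSE)
  left <- association_set(all_pairs[1:10, ], u_d, u_c)
  right <- association_set(all_pairs[11:20, ], u_d, u_c)
  expect_gt(overlap_significance(left, right), 0.95)
  # symmetry
  expect_equal(overlap_significance(left, right),
               overlap_significance(right, left))

  other <- association_set(pairs, diseases, cells[1:10])
  expect_error(overlap_significance(a, other), "universe")
})

test_that("precision, recall and F1 follow their conventions", {
  u_d <- sprintf("d%d", 1:6)
  u_c <- c("c1", "c2")
  all_pairs <- expand.grid(disease = u_d, cell_type = u_c,
                           stringsAsFactors = FALSE)
  truth <- association_set(all_pairs[1:8, ], u_d, u_c)
  expect_equal(unlist(precision_recall_f1(truth, truth)[, 1:3]),
               c(precision = 1, recall = 1, f1 = 1))

  disjoint <- association_set(all_pairs[9:12, ], u_d, u_c)
  expect_equal(unlist(precision_recall_f1(disjoint, truth)[, 1:3]),
               c(precision = 0, recall = 0, f1 = 0))

  pred <- association_set(all_pairs[7:10, ], u_d, u_c)  # 2 of 4 in truth
  prf <- precision_recall_f1(pred, truth)
  expect_equal(prf$precision, 0.5)
  expect_equal(prf$recall, 0.25)
  expect_equal(prf$f1, 1 / 3)

  none <- association_set(all_pairs[0, ], u_d, u_c)
  expect_equal(precision_recall_f1(none, truth)$precision, 0)
})

test_that("disease bins fill greedily with ties kept together", {
  mk <- function(sizes) {
    sets <- lapply(sizes, function(s) sprintf("g%03d", seq_len(s)))
    names(sets) <- sprintf("d%03d", seq_along(sizes))
    sets
  }
  distinct <- make_disease_bins(mk(60:21), min_bin = 20)
  expect_equal(as.integer(table(distinct$bin)), c(20L, 20L))
  expect_true(all(distinct$n_genes[distinct$bin == 1] >
                    max(distinct$n_genes[distinct$bin == 2])))

  tied <- make_disease_bins(mk(c(40:22, 21, 21, 21)), min_bin = 20)
  expect_equal(as.integer(table(tied$bin)), 22L)

  small <- make_disease_bins(mk(c(5, 6, 7)), min_bin = 20)
  expect_true(all(small$bin == 1))
  expect_identical(nrow(make_disease_bins(list())), 0L)
})

test_that("a parameter grid evaluation reports one row per grid point", {
  study <- generate_synthetic_study(n_genes = 120, n_cell_types = 3,
                                    background_edges = 450,
                                    n_diseases = 2, seed = 61)
  grid <- parameter_grid_eval(study$gene_sets, study$edges, study$profiles,
                              study$truth, confidence_cutoffs = c(0, 0.8),
                              restart_probs = c(0.5, 0.7), u = 100,
                              seed = 62)
  expect_identical(nrow(grid), 4L)
  expect_true(all(grid$f1 >= 0 & grid$f1 <= 1))
  # planted structure is recoverable at default-like parameters
  expect_gt(grid$f1[grid$confidence_cutoff == 0.8 &
                      grid$restart_prob == 0.7], 0)

  # a 1x1 grid is exactly one GSC run plus a PRF comparison
  one <- parameter_grid_eval(study$gene_sets, study$edges, study$profiles,
                             study$truth, confidence_cutoffs = 0.8,
                             restart_probs = 0.7, u = 100, seed = 62)
  expect_identical(nrow(one), 1L)
  kept <- study$edges[study$edges$score > 0.8, ]
  res <- adjust_fdr(gsc_test(study$gene_sets, kept, study$profiles,
                             u = 100, r = 0.7, seed = 63))
  manual <- precision_recall_f1(
    association_set(res[res$q_value < 0.1, c("disease", "cell_type")],
                    study$truth$diseases, study$truth$cell_types),
    study$truth
  )
  expect_equal(one$f1, manual$f1)
  expect_equal(one$n_predicted, manual$n_predicted)
})
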