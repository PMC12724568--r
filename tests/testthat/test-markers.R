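test_that("rank_sum_test matches exact enumeration and handles ties", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rank_sum_test(c(5, 5, 5), c(5, 5, 5)), 1.0)
  expect_equal(rank_sum_test(c(1, 2), c(1, 2)), 1.0)
  expect_error(rank_sum_test(numeric(), 1), "empty group")
  # symmetry
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1))
    expect_equal(rank_sum_test(x, y), rank_sum_test(y, x))
  }
})

test_that("exact branch equals exhaustive enumeration over rank assignments", {
  set.seed(2)
  for (i in 1:200) {
    nx <- sample(1:5, 1); ny <- sample(1:5, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    expect_equal(rank_sum_test(x, y), oracle_rank_sum(x, y),
                 info = sprintf("instance %d (nx=%d, ny=%d)", i, nx, ny))
  }
})

test_that("exact and normal-approximation branches agree where decisions
           are made", {
  # near the center of the null the exact two-sided p jumps in coarse
  # increments (up to ~0.13 away from the smooth approximation), so branch
  # agreement is asserted in the significant regime the filters act on
  set.seed(3)
  worst <- 0; n_checked <- 0
  for (i in 1:2000) {
    nx <- sample(3:5, 1); ny <- sample(3:5, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    p_exact <- oracle_rank_sum(x, y)
    if (p_exact > 0.1) next
    p_norm <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    worst <- max(worst, abs(p_exact - min(1, p_norm)))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 100)
  expect_lt(worst, 0.02 + 1e-12)
})

test_that("log_fold_change follows the pseudocount formula", {
  # two groups of one cell each; norm values arranged directly
  counts <- matrix(c(5, 0, 3, 1), 2, 2)
  ds <- log_normalize(make_ds(counts, c("A", "B")))
  a <- cluster_cells(ds, "A"); b <- cluster_cells(ds, "B")
  m_in <- mean(expm1(ds$norm[a, 1])); m_out <- mean(expm1(ds$norm[b, 1]))
  expect_equal(log_fold_change(ds, a, b, ds$gene_ids[1]),
               log((m_in + 1) / (m_out + 1)))
  # equal means give zero exactly
  counts2 <- matrix(c(2, 2, 1, 1), 2, 2)
  ds2 <- log_normalize(make_ds(counts2, c("A", "B")))
  expect_equal(log_fold_change(ds2, cluster_cells(ds2, "A"),
                               cluster_cells(ds2, "B"), ds2$gene_ids[1]), 0)
  # zero in the out-group is finite thanks to the pseudocount
  counts3 <- matrix(c(4, 0, 1, 5), 2, 2)
  ds3 <- log_normalize(make_ds(counts3, c("A", "B")))
  lfc <- log_fold_change(ds3, cluster_cells(ds3, "A"),
                         cluster_cells(ds3, "B"), ds3$gene_ids[1])
  expect_true(is.finite(lfc))
  expect_equal(lfc, log(mean(expm1(ds3$norm[1, 1])) + 1))
  # the 1.28-fold floor sits at lfc 0.25
  expect_equal(log(2.568 / 2.0), 0.25, tolerance = 1e-4)
  expect_error(log_fold_change(ds3, character(), cluster_cells(ds3, "B"),
                               ds3$gene_ids[1]), "empty group")
})

test_that("pct_expressing counts nonzero cells and satisfies the
           weighted-union identity", {
  counts <- matrix(c(0, 1, 3, 2, 0, 0, 0, 0), 4, 2)
  ds <- make_ds(counts, "A")
  expect_equal(pct_expressing(ds, ds$cell_ids, ds$gene_ids[1]), 0.75)
  expect_equal(pct_expressing(ds, ds$cell_ids, ds$gene_ids[2]), 0)
  set.seed(4)
  big <- make_ds(nb_matrix(40, rep(1, 5)), "A")
  for (i in 1:10) {
    split <- sample(40, 17)
    s1 <- big$cell_ids[split]; s2 <- big$cell_ids[-split]
    g <- sample(big$gene_ids, 1)
    expect_equal(pct_expressing(big, big$cell_ids, g),
                 (17 * pct_expressing(big, s1, g) +
                    23 * pct_expressing(big, s2, g)) / 40)
  }
  expect_error(pct_expressing(big, character(), big$gene_ids[1]),
               "empty cell set")
})

test_that("auc_marker counts wins plus half ties", {
  expect_equal(auc_marker(c(10, 11, 12), c(1, 2, 3)), 1.0)
  expect_equal(auc_marker(c(7, 7), c(7, 7, 7)), 0.5)
  expect_equal(auc_marker(c(1, 2, 3), c(2, 3, 4)), 2 / 9, tolerance = 1e-4)
  # brute-force oracle and the complement identity on random data
  set.seed(5)
  for (i in 1:20) {
    x <- sample(0:4, sample(2:6, 1), replace = TRUE)
    y <- sample(0:4, sample(2:6, 1), replace = TRUE)
    wins <- sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
    expect_equal(auc_marker(x, y), wins / (length(x) * length(y)))
    expect_equal(auc_marker(x, y) + auc_marker(y, x), 1)
  }
})

test_that("marker filters are inclusive on fold and pct, strict on p", {
  th <- marker_thresholds()
  # semantic boundary at exact equality (lfc floor, pct gap, p gate)
  stats_at <- tibble::tibble(gene = "probe", lfc = 0.25, p = 0.005,
                             pct_in = 0.6, pct_out = 0.5, auc = NA_real_,
                             tested = TRUE)
  kept <- iectools:::finish_marker_table(stats_at, "best4", th,
                                         both_directions = FALSE,
                                         use_pct_diff = TRUE)
  expect_equal(kept$gene, "probe")
  stats_p <- dplyr::mutate(stats_at, p = 0.01)     # strict on p
  expect_equal(nrow(iectools:::finish_marker_table(stats_p, "best4", th,
                                                   FALSE, TRUE)), 0)
  stats_lfc <- dplyr::mutate(stats_at, lfc = 0.2499)
  expect_equal(nrow(iectools:::finish_marker_table(stats_lfc, "best4", th,
                                                   FALSE, TRUE)), 0)
  # end-to-end: a gene fractionally above the 1.284-fold floor is retained,
  # one at 1.27-fold is excluded
  at_floor <- find_markers(boundary_ds(exp(0.2500001)), "best4", th)
  expect_true("probe" %in% at_floor$gene)
  below <- find_markers(boundary_ds(1.27), "best4", th)
  expect_false("probe" %in% below$gene)
  expect_error(marker_thresholds(min_fold = 1.4),
               "lfc_floor")
  expect_error(marker_thresholds(min_fold = 0.9), "min_fold")
})

test_that("find_markers recovers the planted best4 program", {
  spec <- sim_spec(n_datasets = 2L, conserved_min = 2L, seed = 21L)
  sim <- simulate_multispecies(spec)
  for (d in 1:2) {
    ds <- log_normalize(sim$datasets[[d]])
    mk <- find_markers(ds, "best4")
    planted <- sim$truth$genes |>
      dplyr::filter(.data$dataset_id == names(sim$datasets)[d],
                    .data$planted)
    expect_gte(mean(planted$gene_id %in% mk$gene), 0.9)
    expect_gte(mean(mk$gene %in% planted$gene_id), 0.9)
    expect_true(all(mk$direction == "up"))
  }
})

test_that("all-zero genes never appear and output order is deterministic", {
  set.seed(6)
  counts <- cbind(nb_matrix(60, c(5, 1, 1)), 0L)
  colnames(counts) <- c("up", "g1", "g2", "silent")
  counts[1:30, "up"] <- counts[1:30, "up"] + 20L
  ds <- make_ds(counts, rep(c("best4", "rest"), each = 30))
  mk <- find_markers(ds, "best4")
  expect_false("silent" %in% mk$gene)
  # invariant to cell and gene permutations
  perm_cells <- sample(nrow(counts)); perm_genes <- sample(ncol(counts))
  ds_p <- make_ds(counts[perm_cells, perm_genes],
                  rep(c("best4", "rest"), each = 30)[perm_cells])
  mk_p <- find_markers(ds_p, "best4")
  expect_equal(as.data.frame(mk), as.data.frame(mk_p))
  expect_error(find_markers(ds, "missing"), "cluster not found")
})

test_that("genotype contrasts are calibrated under the null and recover
           planted shifts", {
  set.seed(7)
  n <- 60; g <- 200
  mu <- rlnorm(g, log(2), 0.4)
  wt <- make_ds(nb_matrix(n, mu), "best4", genotype = "WT")
  mutm <- nb_matrix(n, mu)
  rownames(mutm) <- sprintf("m%03d", seq_len(n))
  mut <- make_ds(mutm, "best4", genotype = "MUT")
  # identical distributions: near-nominal rate of p < 0.01 among tested genes
  stats <- iectools:::marker_stats(log_normalize(bind_datasets(wt, mut)),
                                   wt$cell_ids, mut$cell_ids, min_pct = 0.1)
  frac <- mean(stats$p[stats$tested] < 0.01)
  expect_lt(frac, 0.01 + 2 * sqrt(0.01 * 0.99 / sum(stats$tested)) + 1e-9)
  # planted 4-fold shift in 10 genes is recovered with direction
  mu2 <- mu; mu2[1:10] <- mu2[1:10] * 4
  wt2m <- nb_matrix(n, mu2)
  rownames(wt2m) <- sprintf("w%03d", seq_len(n))
  wt2 <- make_ds(wt2m, "best4", genotype = "WT")
  ctr <- contrast_by_cluster(wt2, mut, "best4")
  hits <- ctr$gene[ctr$direction == "up"]
  expect_gte(mean(sprintf("g%03d", 1:10) %in% hits), 0.9)
  # tiny genotype groups refuse to test
  tiny <- subset_cells(mut, mut$cell_ids[1:2])
  expect_error(contrast_by_cluster(wt2, tiny, "best4"), "genotype MUT")
})
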