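test_that("pseudo-bulk equals a dense groupby-sum oracle and is CPM-exact", {
  cm <- random_cm(50, 30, lambda = 2, seed = 4)
  labels <- rep(c("s1", "s2", "s3"), each = 10)
  pb <- aggregate_pseudobulk(cm, labels)
  dense <- as.matrix(cm$counts)
  for (s in unique(labels)) {
    sums <- rowSums(dense[, labels == s, drop = FALSE])
    cpm <- sums / sum(sums) * 1e6
    expect_equal(unname(pb$logcpm[, s]), unname(log2(cpm + 1)))
    expect_equal(sum(2^pb$logcpm[, s] - 1), 1e6, tolerance = 1e-6)
  }
})

test_that("pseudo-bulk is invariant to duplicating every cell", {
  cm <- random_cm(40, 12, lambda = 2, seed = 5)
  labels <- rep(c("a", "b"), each = 6)
  doubled <- count_matrix(cbind(cm$counts, cm$counts),
                          cell_sample = c(labels, labels))
  colnames(doubled$counts) <- sprintf("c%02d", 1:24)
  pb1 <- aggregate_pseudobulk(cm, labels)
  pb2 <- aggregate_pseudobulk(doubled)
  expect_equal(pb1$logcpm, pb2$logcpm)
})

test_that("single-cell samples reduce to that cell's normalized profile", {
  cm <- random_cm(30, 3, lambda = 3, seed = 6)
  pb <- aggregate_pseudobulk(cm, c("x", "y", "z"))
  dense <- as.matrix(cm$counts)
  expect_equal(unname(pb$logcpm[, "x"]),
               unname(log2(dense[, 1] / sum(dense[, 1]) * 1e6 + 1)))
})

test_that("PCA behaves like a centered SVD", {
  cm <- random_cm(60, 20, lambda = 2, seed = 7)
  pb <- aggregate_pseudobulk(cm, rep(sprintf("s%d", 1:5), each = 4))
  pc <- pseudobulk_pca(pb, n_components = 4)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lte(sum(pc$var_explained), 1 + 1e-12)
  # full reconstruction returns the centered matrix
  m <- t(pb$logcpm)
  full <- prcomp(m, center = TRUE)
  rec <- full$x %*% t(full$rotation)
  expect_equal(rec, scale(m, scale = FALSE), ignore_attr = TRUE,
               tolerance = 1e-8)
  # identical samples share PC coordinates
  dup <- cbind(pb$logcpm, dup = pb$logcpm[, 1])
  pc2 <- pseudobulk_pca(dup, n_components = 2)
  expect_equal(pc2$coords[1, ], pc2$coords[ncol(dup), ], ignore_attr = TRUE)
})

test_that("PCA separates groups along the dominant planted axis", {
  # time effect much larger than region effect -> PC1 orders by months
  d <- planted_design(n_cells_per_group = 60, n_genes = 300,
                      n_region_genes = 20, n_time_genes = 40,
                      region_effect = 0.3, time_effect = 2.0, seed = 10)
  g <- simulate_grouped_counts(d)
  pb <- aggregate_pseudobulk(g$matrix)
  pc <- pseudobulk_pca(pb, n_components = 2)
  months <- default_groups()$months[match(rownames(pc$coords),
                                          default_groups()$group)]
  # 4MPT and pre-4MPT samples separate on PC1
  pc1 <- pc$coords[, 1]
  expect_true(max(pc1[months < 4]) < min(pc1[months == 4]) ||
              min(pc1[months < 4]) > max(pc1[months == 4]))
})

test_that("distance clustering is a metric-like summary that finds blocks", {
  cm <- random_cm(50, 20, lambda = 2, seed = 8)
  pb <- aggregate_pseudobulk(cm, rep(sprintf("s%d", 1:5), each = 4))
  dc <- distance_cluster(pb)
  expect_equal(dc$distance, t(dc$distance))
  expect_equal(unname(diag(dc$distance)), rep(0, 5))
  expect_true(all(dc$distance >= 0))

  # planted two-block structure: the top split recovers the blocks
  set.seed(9)
  base1 <- rnorm(100, 5); base2 <- rnorm(100, 5)
  m <- cbind(a1 = base1 + rnorm(100, 0, 0.1), a2 = base1 + rnorm(100, 0, 0.1),
             b1 = base2 + rnorm(100, 0, 0.1), b2 = base2 + rnorm(100, 0, 0.1))
  dc2 <- distance_cluster(m)
  top <- cutree(dc2$hclust, k = 2)
  expect_equal(top[["a1"]], top[["a2"]])
  expect_equal(top[["b1"]], top[["b2"]])
  expect_false(top[["a1"]] == top[["b1"]])
  # identical samples merge at height ~0
  m2 <- cbind(m, a1copy = m[, "a1"])
  dc3 <- distance_cluster(m2)
  expect_lt(dc3$hclust$height[1], 1e-10)

  expect_error(distance_cluster(cbind(m, flat = rep(1, 100))), "flat")
})

test_that("reference correlation is a Spearman map with argmax best match", {
  sim <- simulate_reference_panel(n_refs = 3, n_samples = 3, n_genes = 100,
                                  noise_sd = 0, seed = 13)
  # monotone transform of a reference still correlates 1.0
  q <- exp(sim$panel[, 2, drop = FALSE] / 3)
  colnames(q) <- "mono"
  cm <- correlate_to_reference(q, sim$panel, min_shared = 50)
  expect_equal(cm$rho["mono", "REF02"], 1.0)
  expect_equal(unname(cm$best_match["mono"]), "REF02")
  expect_true(all(cm$rho >= -1 & cm$rho <= 1))

  # noisy recovery vs a brute-force rank-correlation oracle
  noisy <- simulate_reference_panel(n_refs = 4, n_samples = 6, n_genes = 500,
                                    noise_sd = 1, seed = 14)
  cm2 <- correlate_to_reference(noisy$samples, noisy$panel, min_shared = 50)
  oracle <- apply(noisy$samples, 2, function(s)
    colnames(noisy$panel)[which.max(apply(noisy$panel, 2, function(p)
      cor(rank(s), rank(p))))])
  expect_equal(unname(cm2$best_match), unname(oracle))

  expect_error(correlate_to_reference(q, sim$panel, min_shared = 1000),
               "shared genes")
})
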