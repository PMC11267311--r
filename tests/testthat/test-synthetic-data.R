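test_that("contamination-free barnyard singlets have pure species ratios", {
  cfg <- barnyard_config(n_human = 50, n_mouse = 50, n_doublets = 0,
                         ambient_fraction = 0, mean_umis_per_cell = 500,
                         n_genes_per_species = 100, seed = 11)
  sim <- simulate_barnyard(cfg)
  r <- human_ratio(sim$matrix)
  expect_equal(unname(r[sim$truth$true_label == "human"]), rep(1, 50))
  expect_equal(unname(r[sim$truth$true_label == "mouse"]), rep(0, 50))
})

test_that("generators are byte-identical under a repeated seed", {
  cfg <- barnyard_config(n_human = 20, n_mouse = 20, n_doublets = 5,
                         ambient_fraction = 0.05, mean_umis_per_cell = 300,
                         n_genes_per_species = 80, seed = 5)
  s1 <- simulate_barnyard(cfg)
  s2 <- simulate_barnyard(cfg)
  expect_identical(s1$matrix$counts, s2$matrix$counts)
  expect_identical(s1$truth, s2$truth)

  d <- planted_design(n_cells_per_group = 10, n_genes = 60,
                      n_region_genes = 5, n_time_genes = 5, seed = 5)
  expect_identical(simulate_grouped_counts(d)$matrix$counts,
                   simulate_grouped_counts(d)$matrix$counts)
  sc <- skeleton_config(seed = 5)
  expect_identical(simulate_skeleton(sc)$skeleton,
                   simulate_skeleton(sc)$skeleton)
  tc <- trace_config(noise_sd = 2, seed = 5)
  expect_identical(simulate_traces(tc, n_cells = 3)$f,
                   simulate_traces(tc, n_cells = 3)$f)
})

test_that("mouse singlet human-ratio matches the closed-form ambient mean", {
  # replacement model: E[r] = ambient_fraction * ambient human share
  cfg <- barnyard_config(n_human = 0, n_mouse = 2000, n_doublets = 0,
                         ambient_fraction = 0.05, ambient_human_share = 0.5,
                         mean_umis_per_cell = 2000,
                         n_genes_per_species = 300, seed = 7)
  r <- human_ratio(simulate_barnyard(cfg)$matrix)
  expect_equal(mean(r), 0.05 * 0.5, tolerance = 0.05)
})

test_that("barnyard singlet ratio distribution is bimodal with a clean gap", {
  cfg <- barnyard_config(n_human = 500, n_mouse = 500, n_doublets = 0,
                         ambient_fraction = 0.05, mean_umis_per_cell = 2000,
                         n_genes_per_species = 200, seed = 3)
  r <- human_ratio(simulate_barnyard(cfg)$matrix)
  expect_lt(mean(r > 0.2 & r < 0.8), 0.01)
  bim <- ratio_bimodality(r)
  expect_true(bim$bimodal)
  # peaks within one bin (0.02) of the ambient-shifted extremes
  expect_lt(min(abs(bim$peaks - 0.05 * 0.5)), 0.03)
  expect_lt(min(abs(bim$peaks - (1 - 0.05 * 0.5))), 0.03)
})

test_that("null planted design yields an empty truth table and labels all cells", {
  d <- planted_design(n_cells_per_group = 5, n_genes = 40,
                      n_region_genes = 4, n_time_genes = 4,
                      region_effect = 0, time_effect = 0, seed = 2)
  g <- simulate_grouped_counts(d)
  expect_equal(nrow(g$truth), 0)
  expect_false(anyNA(g$matrix$cell_sample))
  expect_equal(sort(unique(g$matrix$cell_sample)),
               sort(default_groups()$group))
  expect_equal(length(g$matrix$cell_sample), ncol(g$matrix$counts))
})

test_that("planted region effect shows up as the expected group-mean ratio", {
  d <- planted_design(n_cells_per_group = 400, n_genes = 200,
                      n_region_genes = 20, n_time_genes = 0,
                      region_effect = 1.0, seed = 9)
  g <- simulate_grouped_counts(d)
  up_pfc <- g$truth$gene[g$truth$effect > 0]
  pfc <- g$matrix$cell_sample == "PFC_4MPT"
  hip <- g$matrix$cell_sample == "HIP_4MPT"
  ratio <- Matrix::rowMeans(g$matrix$counts[up_pfc, pfc]) /
    Matrix::rowMeans(g$matrix$counts[up_pfc, hip])
  expect_equal(mean(ratio), 2^1.0, tolerance = 0.1)
})

test_that("invalid generator configs are rejected", {
  expect_error(barnyard_config(n_human = 0, n_mouse = 0, n_doublets = 0),
               "at least one droplet")
  expect_error(planted_design(nb_dispersion = 0), "dispersion")
  expect_error(planted_design(nb_dispersion = -1), "dispersion")
  expect_error(trace_config(stimulus_time = 100, duration = 60))
  expect_error(skeleton_config(segment_length = 0))
})

test_that("skeleton generator ground truth matches closed forms and edge walk", {
  # single unbranched primary: one segment, one terminal
  s1 <- simulate_skeleton(skeleton_config(n_primary = 1, branching_depth = 1,
                                          segment_length = 25, jitter = 0,
                                          seed = 4))
  expect_equal(s1$truth$total_length, 25, tolerance = 1e-9)
  b1 <- branch_stats(s1$skeleton)
  expect_equal(b1$n_primary, 1)
  expect_equal(b1$n_terminal, 1)

  # two primaries, two levels of bifurcation -> 4 terminals
  s2 <- simulate_skeleton(skeleton_config(n_primary = 2, branching_depth = 2,
                                          segment_length = 10, jitter = 0,
                                          seed = 4))
  expect_equal(branch_stats(s2$skeleton)$n_terminal, 4)

  # random trees: truth length equals an independent edge-walk sum
  for (seed in 1:5) {
    s <- simulate_skeleton(skeleton_config(n_primary = 3, branching_depth = 3,
                                           jitter = 3, seed = seed))
    sk <- s$skeleton
    pidx <- match(sk$parent, sk$id)
    walk <- 0
    for (i in which(sk$parent != -1))
      walk <- walk + sqrt(sum((sk[i, c("x", "y", "z")] -
                               sk[pidx[i], c("x", "y", "z")])^2))
    expect_equal(s$truth$total_length, walk, tolerance = 1e-9)
  }
})

test_that("neurite point generator hits its target coverage and extremes", {
  sk <- straight_skeleton(100, step = 10)
  full <- simulate_neurite_points(sk, 1, offset = 0, seed = 1)
  expect_equal(full$truth_fraction, 1.0)
  expect_equal(colocalization(sk, full$points, eps = 0.2)$total_fraction, 1.0)

  none <- simulate_neurite_points(sk, 0, seed = 1)
  expect_equal(nrow(none$points), 0)
  expect_equal(none$truth_fraction, 0)
  expect_equal(colocalization(sk, none$points, eps = 0.2)$total_fraction, 0)

  half <- simulate_neurite_points(sk, 0.5, offset = 0, seed = 2)
  expect_equal(half$truth_fraction, 0.5, tolerance = 0.01)
})

test_that("trace generator plants amplitude, onset and sub-threshold cases", {
  # flat trace: no response possible
  flat <- simulate_traces(trace_config(amplitude_fraction = 0, noise_sd = 0),
                          n_cells = 1)
  expect_true(all(flat$f == flat$f[1]))

  # instantaneous rise: criterion crossed at the first post-stimulus sample
  step <- simulate_traces(trace_config(amplitude_fraction = 0.5,
                                       rise_time = 0, noise_sd = 0),
                          n_cells = 1)
  r <- detect_response(dff(step))
  expect_true(r$responded)
  expect_equal(r$response_time, 0.1)

  # planted amplitude below the 10% criterion never crosses it
  sub <- simulate_traces(trace_config(amplitude_fraction = 0.09,
                                      rise_time = 0, noise_sd = 0),
                         n_cells = 1)
  expect_false(detect_response(dff(sub))$responded)
})

test_that("noiseless reference panel recovers its truth map exactly", {
  sim <- simulate_reference_panel(n_refs = 4, n_samples = 8, n_genes = 120,
                                  noise_sd = 0, seed = 6)
  cm <- correlate_to_reference(sim$samples, sim$panel, min_shared = 50)
  expect_equal(unname(cm$best_match[sim$truth$sample]),
               sim$truth$reference)
  for (i in seq_len(nrow(sim$truth)))
    expect_equal(cm$rho[sim$truth$sample[i], sim$truth$reference[i]], 1.0)
})
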