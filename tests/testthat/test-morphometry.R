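test_that("a straight radial process crosses every sphere below its tip once", {
  sk <- straight_skeleton(100, step = 100)  # soma + one node at 100 um
  pr <- sholl(sk, radius_step = 10)
  expect_equal(pr$crossings[pr$radius < 100], rep(1L, 9))
  expect_equal(pr$crossings[pr$radius >= 100], rep(0L, sum(pr$radius >= 100)))
})

test_that("a soma-only skeleton has an all-zero profile", {
  soma <- as_skeleton(data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                                 radius = 5, parent = -1))
  pr <- sholl(soma, radius_step = 5, max_radius = 20)
  expect_equal(pr$crossings, rep(0L, 4))
})

test_that("sholl equals the dense-sampling oracle on random trees", {
  for (seed in 1:10) {
    s <- simulate_skeleton(skeleton_config(n_primary = 3, branching_depth = 3,
                                           segment_length = 15, jitter = 2,
                                           seed = seed))
    pr <- sholl(s$skeleton, radius_step = 5)
    oracle <- sholl_dense_oracle(s$skeleton, pr$radius, step = 0.05)
    expect_equal(pr$crossings, oracle)
  }
})

test_that("sholl is invariant under rigid rotation and translation", {
  s <- simulate_skeleton(skeleton_config(n_primary = 4, branching_depth = 3,
                                         seed = 3))
  sk <- s$skeleton
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(sk[, c("x", "y", "z")]) %*% t(rot)
  sk2 <- sk
  sk2$x <- xyz[, 1] + 12.5; sk2$y <- xyz[, 2] - 3; sk2$z <- xyz[, 3] + 40
  sk2 <- as_skeleton(sk2)
  p1 <- sholl(sk, radius_step = 5, max_radius = 100)
  p2 <- sholl(sk2, radius_step = 5, max_radius = 100)
  expect_equal(p1$crossings, p2$crossings)
})

test_that("branch statistics match closed forms and generator truth", {
  # single segment
  one <- straight_skeleton(40, step = 40)
  b <- branch_stats(one)
  expect_equal(b$total_length, 40)
  expect_equal(b$n_primary, 1)
  expect_equal(b$n_terminal, 1)
  expect_equal(b$soma_area, pi * 25)

  # simulated skeletons match their ground truth exactly
  for (seed in 1:20) {
    s <- simulate_skeleton(skeleton_config(
      n_primary = sample(1:5, 1), branching_depth = sample(1:4, 1),
      jitter = runif(1, 0, 3), seed = seed))
    b <- branch_stats(s$skeleton)
    expect_equal(b$total_length, s$truth$total_length, tolerance = 1e-12)
    expect_equal(b$n_primary, s$truth$n_primary)
    expect_equal(b$n_terminal, s$truth$n_terminal)
    expect_equal(b$soma_area, s$truth$soma_area)
  }
})

test_that("malformed skeletons are rejected", {
  expect_error(as_skeleton(data.frame(id = 1:2, type = 3, x = 0, y = 0,
                                      z = 0, radius = 1, parent = c(2, 1))),
               "root")
  expect_error(as_skeleton(data.frame(id = 1:3, type = c(1, 3, 3),
                                      x = 0, y = 0, z = 0, radius = 1,
                                      parent = c(-1, 1, 9))),
               "orphan")
})

test_that("proximal-only coverage splits cleanly at the 40 um boundary", {
  # radial segment 0-80 um; evidence points only along 0-40 um
  sk <- straight_skeleton(80, step = 10)
  pts <- data.frame(x = seq(0.25, 39.75, by = 0.5), y = 0, z = 0)
  res <- colocalization(sk, pts, eps = 0.3, boundary = 40)
  expect_equal(res$proximal_fraction, 1.0)
  expect_equal(res$distal_fraction, 0.0)
  expect_equal(res$proximal_length, 40)
  expect_equal(res$distal_length, 40)
})

test_that("coverage fractions and the length-weighted identity hold", {
  sk <- straight_skeleton(100, step = 10)
  # points covering the first half at sub-segment midpoints
  pts <- data.frame(x = seq(0.25, 49.75, by = 0.5), y = 0, z = 0)
  res <- colocalization(sk, pts, eps = 0.2, boundary = 40)
  expect_equal(res$total_fraction, 0.5, tolerance = 0.01)
  recon <- (res$proximal_fraction * res$proximal_length +
            res$distal_fraction * res$distal_length) / res$total_length
  expect_equal(res$total_fraction, recon, tolerance = 1e-9)

  # halving the discretization step barely moves the fractions
  fine <- colocalization(sk, pts, eps = 0.2, boundary = 40, step = 0.25)
  expect_lt(abs(fine$total_fraction - res$total_fraction), 0.01)

  # generous coverage saturates; empty point cloud gives zero
  dense_pts <- data.frame(x = seq(0, 100, by = 0.25), y = 0, z = 0)
  expect_equal(colocalization(sk, dense_pts, eps = 1)$total_fraction, 1.0)
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric())
  expect_equal(colocalization(sk, empty, eps = 1)$total_fraction, 0)
})

test_that("simulated coverage truth is recovered by the colocalization scorer", {
  for (seed in 1:5) {
    s <- simulate_skeleton(skeleton_config(n_primary = 3, branching_depth = 3,
                                           seed = seed))
    np <- simulate_neurite_points(s$skeleton, 0.5, offset = 0, seed = seed)
    res <- colocalization(s$skeleton, np$points, eps = 0.2)
    expect_equal(res$total_fraction, np$truth_fraction, tolerance = 0.05)
  }
})
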