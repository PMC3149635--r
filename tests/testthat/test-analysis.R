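test_that("the quadratic energy has its trivial zeros and cue term", {
  n <- 20
  expect_equal(network_energy(matrix(0, n, n), runif(n)), 0)
  set.seed(20)
  w <- matrix(rnorm(n * n), n, n)
  expect_equal(network_energy(w, rep(0, n)), 0)
  u <- runif(n)
  I <- runif(n, -1, 1)
  expect_equal(network_energy(w, u, I),
               network_energy(w, u) - sum(I * u))
})

test_that("stored patterns sit lower in energy than random states", {
  set.seed(21)
  w <- trained_shock_only()
  e_pat <- network_energy(w, default_ps$x[2, ])
  e_rand <- replicate(100, {
    u <- numeric(100)
    u[sample.int(100, 14)] <- 1
    network_energy(w, u)
  })
  expect_lt(e_pat, median(e_rand))
})

test_that("the MDA projection spans the between-pattern plane", {
  ps <- default_ps
  proj <- mda_projection(ps)
  expect_equal(nrow(proj$basis), 2)  # P - 1 = 2 for 3 patterns
  expect_equal(proj$basis %*% t(proj$basis), diag(2), tolerance = 1e-10)
  # rank of the scatter never exceeds P - 1
  centered <- sweep(ps$x, 2, colMeans(ps$x))
  expect_lte(qr(crossprod(centered))$rank, 2)
  # distinct patterns project to distinct points
  pc <- proj$pattern_coords
  d <- as.matrix(dist(pc))
  expect_true(all(d[upper.tri(d)] > 0.5))
  # patterns live in the scatter subspace, so the projection preserves
  # their pairwise distances exactly
  expect_equal(as.matrix(dist(pc)), as.matrix(dist(centered)),
               tolerance = 1e-8)
})

test_that("degenerate pattern sets are flagged", {
  x <- rbind(rep(1, 10), rep(1, 10), c(rep(1, 5), rep(0, 5)))
  expect_warning(proj <- mda_projection(x), "rank-deficient")
  expect_lt(nrow(proj$basis), 2)
  expect_error(mda_projection(x[1, , drop = FALSE]), "at least 2")
})

test_that("the landscape is flat for an untrained network and has basins
           at the learned patterns after training", {
  set.seed(22)
  L0 <- energy_landscape(zero_weights(100), default_ps, n_samples = 300,
                         grid_res = 15)
  expect_equal(max(L0$energy) - min(L0$energy), 0)
  expect_true(any(L0$n_in_cell == 0))  # empty cells flagged, not dropped

  w <- trained_w12()
  L <- energy_landscape(w, default_ps, n_samples = 1200, grid_res = 30)
  pc <- attr(L, "pattern_coords")
  e_at <- vapply(1:3, function(i) {
    d2 <- (L$x - pc[i, 1])^2 + (L$y - pc[i, 2])^2
    L$energy[which.min(d2)]
  }, numeric(1))
  # minima at the two learned memories, none at the never-learned one
  # (<= with a tiny slack: the pattern cells can BE the low quantile)
  expect_lte(e_at[1], quantile(L$energy, 0.2) + 1e-4)
  expect_lte(e_at[2], quantile(L$energy, 0.2) + 1e-4)
  expect_gt(e_at[3], median(L$energy) - 1)
  expect_gt(e_at[3], max(e_at[1:2]) + 10)
})

test_that("capacity estimation is reproducible and trivially correct at
           one pattern", {
  c1 <- capacity_curve(n_sizes = 60, p_counts = 1, n_trials = 20, seed = 1)
  expect_equal(c1$success_frac, 1)
  c2 <- capacity_curve(n_sizes = 60, p_counts = c(2, 4), n_trials = 15,
                       seed = 9)
  c3 <- capacity_curve(n_sizes = 60, p_counts = c(2, 4), n_trials = 15,
                       seed = 9)
  expect_identical(c2, c3)
  expect_true(all(c2$success_frac >= 0 & c2$success_frac <= 1))
  expect_error(capacity_curve(n_sizes = 60, p_counts = 2, n_trials = 0))
})
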