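test_that("activation drive matches the closed form", {
  n <- 10
  w0 <- matrix(0, n, n)
  u <- runif(n)
  expect_equal(activation_drive(w0, u, rep(0, n)), rep(0.5, n))
  g_hi <- activation_drive(w0, u, rep(5, n))
  g_lo <- activation_drive(w0, u, rep(-5, n))
  expect_equal(g_hi, rep(0.5 * (1 + tanh(5)), n))  # ~0.99995
  expect_equal(g_hi + g_lo, rep(1, n))  # odd symmetry of tanh
  expect_true(all(g_hi > 0 & g_hi < 1))
  # arbitrary coupling: direct evaluation of the formula
  set.seed(1)
  w <- matrix(rnorm(n * n, sd = 0.3), n, n)
  I <- runif(n, -5, 5)
  expect_equal(activation_drive(w, u, I),
               0.5 * (1 + tanh(drop(w %*% u) + I)))
})

test_that("dimension mismatches name the offending argument", {
  w <- matrix(0, 4, 4)
  expect_error(activation_drive(w, rep(0.5, 3), rep(0, 4)), "'u'")
  expect_error(activation_drive(w, rep(0.5, 4), rep(0, 3)), "'I'")
  expect_error(relax(w, rep(0, 4), rep(0.5, 5)), "'u0'")
  expect_error(relax(w, rep(0, 5), rep(0.5, 5)), "'I'")
  expect_error(relax(w, rep(0, 4), rep(1.5, 4)), "\\[0, 1\\]")
})

test_that("zero-coupling relaxation reaches the closed-form fixed point", {
  # u* = (1 + tanh(I))/2 elementwise, for arbitrary cue currents
  set.seed(42)
  n <- 30
  w0 <- matrix(0, n, n)
  for (rep in 1:10) {
    I <- runif(n, -5, 5)
    res <- relax(w0, I, runif(n), model_params())
    expect_true(res$converged)
    expect_equal(res$u, 0.5 * (1 + tanh(I)), tolerance = 1e-4)
  }
  # no cue: unique fixed point at 0.5
  res <- relax(w0, rep(0, n), runif(n))
  expect_equal(res$u, rep(0.5, n), tolerance = 1e-4)
})

test_that("activations stay within [0, 1] throughout integration", {
  # step through a strongly-coupled relaxation one Euler step at a time
  set.seed(7)
  w <- trained_w12()
  p1 <- model_params(t_relax = 0.1)  # exactly one dt step per call
  u <- runif(100, 0, 0.1)
  I <- mixed_cue(6, default_ps)
  for (step in 1:80) {
    u <- relax(w, I, u, p1)$u
    expect_true(all(u >= 0 & u <= 1))
  }
})

test_that("halving the integration step barely moves the relaxed state", {
  set.seed(8)
  w <- trained_w12()
  I <- test_cue(default_ps)
  u0 <- runif(100, 0, 0.1)
  p <- model_params()
  p_half <- model_params(dt = p$dt / 2)
  u_a <- relax(w, I, u0, p)$u
  u_b <- relax(w, I, u0, p_half)$u
  expect_lt(max(abs(u_a - u_b)), 10 * p$tol)
})

test_that("attractor classification follows the correlation rule", {
  ps <- default_ps
  # exact stored pattern: self-correlation 1
  expect_identical(classify_attractor(ps$x[2, ], ps), 2L)
  expect_identical(classify_attractor(ps$x[1, ], ps), 1L)
  # constant state: correlation undefined -> NONE
  expect_identical(classify_attractor(rep(0.5, 100), ps), NA_integer_)
  # one active neuron dropped still classifies as the same pattern
  u <- ps$x[2, ]
  u[ps$shock_idx[1]] <- 0
  expect_gt(cor(u, ps$x[2, ]), 0.7)  # sanity on the margin at N = 100
  expect_identical(classify_attractor(u, ps), 2L)
  # uncorrelated state falls below any reasonable threshold
  set.seed(2)
  expect_identical(classify_attractor(runif(100), ps, 0.7), NA_integer_)
  expect_error(classify_attractor(ps$x[2, ], ps, 0), "r_threshold")
})
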