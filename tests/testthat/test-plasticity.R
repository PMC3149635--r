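test_that("HLP and MID reproduce the binary case table exhaustively", {
  S <- 0.8
  D <- 1.25
  for (u_i in c(0, 1)) for (u_j in c(0, 1)) for (i_hat_j in c(0, 1)) {
    u <- c(u_i, u_j)
    i_hat <- c(u_i, i_hat_j)  # presynaptic cue agrees; only post matters
    hlp <- hlp_matrix(u, S)
    mid <- mid_matrix(u, mismatch_vector(i_hat, u), D)
    expect_equal(hlp[2, 1], hlp_oracle(u_i, u_j, S),
                 info = sprintf("HLP u_i=%d u_j=%d", u_i, u_j))
    expect_equal(mid[2, 1], mid_oracle(u_i, u_j, i_hat_j, D),
                 info = sprintf("MID u_i=%d u_j=%d i_hat_j=%d",
                                u_i, u_j, i_hat_j))
    expect_true(all(hlp %in% c(-S, 0, S)))
    expect_true(all(mid %in% c(-D, 0, D)))
  }
})

test_that("cue normalization is the stated affine map", {
  expect_equal(normalize_cue(c(-5, 0, 5), 5), c(0, 0.5, 1))
  expect_equal(normalize_cue(2, 4), 0.75)
  expect_error(normalize_cue(1, 0), "I_max")
  # round trip: normalized training cue recovers the binary pattern
  p <- default_ps$x[2, ]
  expect_equal(normalize_cue(training_cue(p, 5), 5), p)
})

test_that("no mismatch means no degradation", {
  set.seed(3)
  u <- runif(50)
  expect_equal(mid_matrix(u, rep(0, 50), 1.25), matrix(0, 50, 50))
  # initial learning: full cue clamps the state, so MID vanishes
  p <- model_params()
  cue <- training_cue(default_ps$x[2, ], p$I_max)
  st <- relax(zero_weights(100), cue, runif(100, 0, 0.1), p)$u
  m <- mismatch_vector(normalize_cue(cue, p$I_max), st)
  expect_lt(max(abs(m)), 1e-3)
  expect_lt(max(abs(mid_matrix(st, m, p$D))), 2e-3)
})

test_that("silent presynaptic neurons change nothing", {
  set.seed(4)
  u <- runif(20)
  silent <- c(3, 11, 17)
  u[silent] <- 0
  m <- runif(20, -1, 1)
  expect_true(all(hlp_matrix(u, 0.8)[, silent] == 0))
  expect_true(all(mid_matrix(u, m, 1.25)[, silent] == 0))
})

test_that("drug overrides zero their plasticity term exactly", {
  set.seed(5)
  u <- runif(30)
  m <- runif(30, -1, 1)
  expect_identical(hlp_matrix(u, 0), matrix(0, 30, 30))   # anisomycin
  expect_identical(mid_matrix(u, m, 0), matrix(0, 30, 30))  # deg. blockade
})

test_that("weights saturate at s0 under arbitrary update sequences", {
  set.seed(6)
  n <- 40
  s0 <- 1
  w <- zero_weights(n)
  for (i in 1:25) {
    u <- round(runif(n))  # binary states give the extreme +/-S, +/-D steps
    i_hat <- round(runif(n))
    hlp <- hlp_matrix(u, runif(1, 0, 1.2))
    mid <- mid_matrix(u, mismatch_vector(i_hat, u), runif(1, 0, 1.5))
    w <- update_weights(w, hlp, mid, s0)
    expect_true(all(abs(w) <= s0))
    expect_true(all(diag(w) == 0))
  }
})

test_that("the session update clips and re-zeroes the diagonal", {
  w <- matrix(0.9, 2, 2)
  hlp <- matrix(0.8, 2, 2)
  out <- update_weights(w, hlp, 0, 1)
  expect_equal(out[2, 1], 1)      # 0.9 + 0.8 truncated to s0
  expect_equal(out[1, 1], 0)
  out2 <- update_weights(-w, -hlp, 0, 1)
  expect_equal(out2[2, 1], -1)    # symmetric truncation at -s0
  w3 <- matrix(c(0, 0.3, -0.2, 0.5), 2, 2)
  expect_equal(update_weights(w3, 0, 0, 1),
               matrix(c(0, 0.3, -0.2, 0), 2, 2))  # identity + zero diag
})

test_that("inter-session decay is multiplicative", {
  w <- matrix(c(0, 1, -0.4, 0), 2, 2)
  expect_equal(apply_decay(w, 0.15), 0.85 * w)
  expect_equal(apply_decay(w, 0), w)
  expect_equal(apply_decay(zero_weights(3), 0.15), zero_weights(3))
  expect_error(apply_decay(w, 1), "gamma")
  expect_error(apply_decay(w, -0.1), "gamma")
})
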