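test_that("sigmoid is a proper threshold function", {
  expect_equal(sigmoid(0, 4), 0.5)
  expect_equal(sigmoid(1e3, 4), 1)
  expect_equal(sigmoid(-1e3, 4), 0)
  # odd symmetry about the threshold
  set.seed(1)
  x <- rnorm(50, sd = 3)
  expect_equal(sigmoid(x, 2.5) + sigmoid(-x, 2.5), rep(1, 50))
  # strictly increasing
  xs <- sort(x)
  expect_true(all(diff(sigmoid(xs, 4)) > 0))
  expect_error(sigmoid(0, 0))
})

test_that("gaussian kernel is symmetric and integral-normalized", {
  p <- test_params()
  g <- field_grid(p)
  k <- gaussian_kernel(2.5, 6, g)
  expect_equal(k$weights, rev(k$weights))
  expect_equal(which.max(k$weights), (length(k$weights) + 1) / 2)
  # discretized integral equals the amplitude (closed-form Gaussian integral)
  expect_equal(sum(k$weights) * g$spacing, 2.5, tolerance = 1e-6)
  expect_equal(gaussian_kernel(0, 6, g)$weights, rep(0, length(k$weights)))
  expect_error(gaussian_kernel(1, -1, g), "width")
})

test_that("effective input weakens with adaptation and clips at zero", {
  s <- c(0, 1, 2, 5)
  expect_equal(effective_input(s, rep(0, 4), 0.6), s)
  expect_equal(effective_input(c(3, 3), c(1, 1), 1), c(0, 0))
  # monotone: more adaptation never increases the input
  set.seed(2)
  for (i in 1:20) {
    raw <- runif(10, 0, 6)
    a1 <- runif(10)
    a2 <- pmin(1, a1 + runif(10, 0, 0.3))
    expect_true(all(effective_input(raw, a2, 0.7) <= effective_input(raw, a1, 0.7)))
  }
})

test_that("field relaxes to the resting state without input, noise, or trace", {
  p <- det_params()
  raw <- numeric(p$n_points)
  # settle to the true resting fixed point (h_u up to the sigmoid-tail
  # correction of order f(beta * h_v))
  st <- resting_state(p, n_offset = 0)
  for (i in seq_len(round(20 * p$tau_u / p$dt))) st <- step(st, raw, p)
  expect_lt(max(abs(st$u - p$h_u)), 5e-3)
  expect_lt(max(abs(st$v - p$h_v)), 5e-3)
  base <- st
  # a perturbed state relaxes back to that fixed point
  st$u <- st$u + 0.5
  for (i in seq_len(round(20 * p$tau_u / p$dt))) st <- step(st, raw, p)
  expect_lt(max(abs(st$u - base$u)), 1e-6)
  expect_lt(max(abs(st$v - base$v)), 1e-6)
})

test_that("compiled integrator matches the reference R update step for step", {
  p <- test_params()
  prot <- single_frame_protocol(4.7, duration = 25)
  rec <- simulate_frames(prot, p, seed = 99, record_stride = p$dt)
  # replay in R with the identical RNG stream
  set.seed(99)
  n0 <- rnorm(1, 0, p$noise_slow_amp)
  st <- resting_state(p, n_offset = n0)
  raw <- input_field(0, 4.7, p)
  for (i in 1:25) st <- step(st, raw, p)
  expect_equal(as.numeric(rec$u_trace[nrow(rec$u_trace), ]), st$u, tolerance = 1e-10)
  expect_equal(rec$final_state$n, st$n, tolerance = 1e-12)
  expect_equal(rec$final_state$m, st$m, tolerance = 1e-10)
  expect_equal(rec$final_state$a, st$a, tolerance = 1e-10)
})

test_that("weak input leaves no trace; stronger input self-excites and leaves one", {
  p <- det_params()
  # weak: subthreshold bump, no trace, returns to rest after removal
  weak <- visfield:::new_protocol(
    rbind(visfield:::frame_row(360, "object", judge_center = 0),
          visfield:::frame_row(360, "blank")),
    list(data.frame(center = 0, amplitude = 3.0), visfield:::no_input()),
    1L, "object", NA_real_)
  rec_w <- simulate_frames(weak, p, seed = 1, record_stride = 0)
  expect_equal(rec_w$frac_supra[1], 0)
  expect_equal(max(rec_w$final_state$m), 0)
  expect_lt(max(abs(rec_w$final_state$u - p$h_u)), 1e-3)

  # strong: suprathreshold peak exceeding input + resting level, trace formed,
  # activation stays above the resting level after stimulus removal
  strong <- visfield:::new_protocol(
    rbind(visfield:::frame_row(360, "object", judge_center = 0),
          visfield:::frame_row(360, "blank")),
    list(data.frame(center = 0, amplitude = 5.2), visfield:::no_input()),
    1L, "object", NA_real_)
  rec_s <- simulate_frames(strong, p, seed = 1, record_stride = 2)
  expect_gt(rec_s$frac_supra[1], 0.5)
  peak <- max(rec_s$u_trace[rec_s$frame_index == 1, ])
  expect_gt(peak, p$h_u + 5.2)          # self-excitation signature
  expect_gt(max(rec_s$final_state$m), 0.05)
  expect_gt(max(rec_s$final_state$u), p$h_u + 0.05)
})

test_that("memory trace never builds below threshold and stays non-negative", {
  p <- test_params()
  prot <- visfield:::new_protocol(
    rbind(visfield:::frame_row(300, "object", judge_center = 0),
          visfield:::frame_row(300, "blank")),
    list(data.frame(center = 0, amplitude = 5.2), visfield:::no_input()),
    1L, "object", NA_real_)
  set.seed(3)
  n0 <- rnorm(1, 0, p$noise_slow_amp)
  st <- resting_state(p, n_offset = n0)
  raw <- input_field(0, 5.2, p)
  for (i in 1:400) {
    sub <- st$u <= 0
    m_prev <- st$m
    st <- step(st, if (i <= 300) raw else numeric(p$n_points), p)
    expect_true(all(st$m >= 0))
    expect_true(all(st$m[sub] <= m_prev[sub] + 1e-12))
  }
})

test_that("simulation is deterministic given the seed and protocol", {
  p <- test_params()
  prot <- single_frame_protocol(4.7, duration = 200)
  r1 <- simulate_frames(prot, p, seed = 7, record_stride = 2)
  r2 <- simulate_frames(prot, p, seed = 7, record_stride = 2)
  expect_identical(r1$u_trace, r2$u_trace)
  expect_identical(r1$final_state, r2$final_state)
})

test_that("with noise ablated, outcomes are seed-independent", {
  p <- det_params()
  prot <- single_frame_protocol(5.0, duration = 300)
  r1 <- simulate_frames(prot, p, seed = 1, record_stride = 0)
  r2 <- simulate_frames(prot, p, seed = 12345, record_stride = 0)
  expect_identical(r1$frac_supra, r2$frac_supra)
  expect_identical(r1$final_state$u, r2$final_state$u)
})

test_that("empty protocols and divergence are handled", {
  p <- test_params()
  empty <- visfield:::new_protocol(
    visfield:::frame_row(1, "object")[0, ], list(), 1L, "object", NA_real_)
  rec <- simulate_frames(empty, p, seed = 1)
  expect_equal(nrow(rec$u_trace), 1)
  # overflowing input makes the state non-finite and is reported as such
  prot <- visfield:::new_protocol(
    visfield:::frame_row(50, "object", judge_center = 0),
    list(data.frame(center = c(0, 0), amplitude = c(1e308, 1e308))),
    1L, "object", NA_real_)
  expect_error(simulate_frames(prot, p, seed = 1), "diverged.*'u'")
})
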