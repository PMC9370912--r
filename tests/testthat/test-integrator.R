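# RK4 stepping, delay buffering, trajectory integration, rendering.

test_that("rk4_step matches the closed-form exponential to fifth order", {
  # one step of dx/dt = -x from 1 with h = 0.1: the RK4 polynomial gives
  # 1 - h + h^2/2 - h^3/6 + h^4/24 = 0.9048375
  x1 <- rk4_step(function(t, s) -s, 1, 0, 0.1)
  expect_equal(x1, 0.9048375, tolerance = 1e-12)
  expect_equal(x1, exp(-0.1), tolerance = 1e-7)
  # zero derivative leaves any state unchanged
  s <- c(1.5, -2, 0.25)
  expect_identical(rk4_step(function(t, x) x * 0, s, 3, 0.7), s)
  # constant derivative advances exactly by c * h
  expect_equal(rk4_step(function(t, x) 2.5, 1, 0, 0.2), 1.5)
  expect_error(rk4_step(function(t, x) NaN, 1, 0, 0.1),
               class = "ecgsim_integration_error")
})

test_that("rk4 global error on dx/dt = -x shrinks ~16x per halving", {
  err <- vapply(c(0.1, 0.05, 0.025, 0.0125), function(h) {
    x <- 1
    for (i in seq_len(round(1 / h))) x <- rk4_step(function(t, s) -s, x, 0, h)
    abs(x - exp(-1))
  }, numeric(1))
  ratios <- err[-length(err)] / err[-1]
  expect_true(all(ratios > 12 & ratios < 20))
})

test_that("delay buffer resolves offsets by rounding tau / step", {
  buf <- delay_buffer(max_delay = 0.1, step = 0.001, init = -1)
  expect_equal(buf$capacity, 100L)
  for (i in 0:120) buffer_push(buf, i)
  now <- 0.120
  # tau = 0.092 -> offset of 92 samples
  expect_equal(delay_lookup(buf, 0.092, now), 120 - 92)
  expect_equal(delay_lookup(buf, 0, now), 120) # tau = 0: current value
  expect_equal(delay_lookup(buf, 0.0924, now), 120 - 92) # nearest rounding
  expect_error(delay_lookup(buf, 0.2, now), "capacity")

  # lookups reaching before the first sample return the constant history
  buf2 <- delay_buffer(0.05, 0.001, init = 7)
  buffer_push(buf2, 1); buffer_push(buf2, 2)
  expect_equal(delay_lookup(buf2, 0.03, 0.001), 7)
})

test_that("integration preserves exact equilibria and is deterministic", {
  p <- get_preset("reaction_diffusion", "normal")$params
  z <- setNames(rep(0, 4), paste0("x", 1:4))
  tr <- integrate_model("reaction_diffusion", p, duration = 1, init = z)
  expect_true(all(tr$state == 0))

  t1 <- integrate_model("reaction_diffusion", p, duration = 5)
  t2 <- integrate_model("reaction_diffusion", p, duration = 5)
  expect_identical(t1$state, t2$state)

  pq <- get_preset("quasi_periodic", "atrial_fibrillation")$params
  a1 <- integrate_model("quasi_periodic", pq, duration = 6, seed = 11L)
  a2 <- integrate_model("quasi_periodic", pq, duration = 6, seed = 11L)
  a3 <- integrate_model("quasi_periodic", pq, duration = 6, seed = 12L)
  expect_identical(a1$state, a2$state)
  expect_false(identical(a1$state, a3$state))
})

test_that("compiled cores agree with the R reference integrator", {
  for (m in c("heterogeneous", "reaction_diffusion", "ring", "quasi_periodic")) {
    p <- get_preset(m, "normal")$params
    fast <- integrate_model(m, p, duration = 1.5)
    ref <- integrate_reference(m, p, duration = 1.5)
    expect_lt(max(abs(fast$state - ref$state)), 1e-12)
  }
})

test_that("integration aborts with a diagnostic on non-finite states", {
  p <- get_preset("reaction_diffusion", "normal")$params
  huge <- setNames(c(1e8, 1e8, -1e8, 1e8), paste0("x", 1:4))
  expect_error(
    integrate_model("reaction_diffusion", p, duration = 1, init = huge),
    class = "ecgsim_integration_error"
  )
})

test_that("step must resolve the smallest positive delay", {
  p <- get_preset("heterogeneous", "normal")$params # tau = 0.092
  expect_error(integrate_model("heterogeneous", p, duration = 1, step = 0.1),
               "delay")
})

test_that("rendering compresses time, resamples, and calibrates gain", {
  ps <- qp_single_kernel(hr = 60)
  tr <- integrate_model("quasi_periodic", ps, duration = 40)

  r1 <- render_trace(tr, time_scale = 1, gain = 1, fs = 250, transient = 5)
  r3 <- render_trace(tr, time_scale = 3, gain = 1, fs = 250, transient = 5 / 3)
  b1 <- estimate_beat_rate(r1)
  b3 <- estimate_beat_rate(r3)
  expect_equal(b3$bpm / b1$bpm, 3, tolerance = 0.02)

  # gain calibration: detected R-peak magnitude equals the requested gain
  r2 <- render_trace(tr, gain = 2, fs = 500, transient = 5)
  expect_equal(max(abs(r2[[2]] - median(r2[[2]]))), 2, tolerance = 1e-9)

  # doubling fs doubles the sample count (+-1) and agrees at shared times
  ra <- render_trace(tr, gain = 1, fs = 250, transient = 5)
  rb <- render_trace(tr, gain = 1, fs = 500, transient = 5)
  expect_lte(abs(nrow(rb) - 2 * nrow(ra)), 1)
  # shared time points agree up to the (fs-dependent) peak-sampling term in
  # the gain calibration
  shared <- rb[seq(1, nrow(rb), by = 2), ]
  expect_equal(shared[[2]][1:nrow(ra)], ra[[2]], tolerance = 2e-3)

  # flat composition falls back to unit scale with a warning
  p0 <- qp_single_kernel(a = 0)
  tr0 <- integrate_model("quasi_periodic", p0, duration = 10,
                         init = setNames(c(1, 0, 0, 0, 0),
                                         c("x", "y", "P", "C", "T")))
  expect_warning(render_trace(tr0, gain = 1, transient = 1), "flat")
})

test_that("tachogram draws are seeded, scaled, and leave the RNG alone", {
  spec <- rr_tachogram_spec(hr_mean = 75, hr_std = 6)
  r1 <- rr_tachogram(spec, 400, seed = 5L)
  r2 <- rr_tachogram(spec, 400, seed = 5L)
  expect_identical(r1, r2)
  expect_equal(mean(r1), 60 / 75, tolerance = 0.05)
  expect_gt(stats::sd(r1), 0)
  # global RNG state is preserved
  set.seed(99); before <- .Random.seed
  invisible(rr_tachogram(spec, 100, seed = 1L))
  expect_identical(.Random.seed, before)
  # zero variability degenerates to the constant mean interval
  expect_identical(rr_tachogram(rr_tachogram_spec(60, 0), 10), rep(1, 10))
})
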