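# Right-hand sides and composition maps of the four models.

het_normal <- function() get_preset("heterogeneous", "normal")$params
rd_normal <- function() get_preset("reaction_diffusion", "normal")$params
ring_normal <- function() get_preset("ring", "normal")$params
qp_normal <- function() get_preset("quasi_periodic", "normal")$params

test_that("heterogeneous derivatives: origin equilibrium and step gating", {
  p <- het_normal()
  expect_identical(heterogeneous_deriv(rep(0, 14), p), rep(0, 14))

  # stimulation currents gate on the sign of the driving velocity:
  # Y3 = y3 drives the QRS channel with C3 = 9e-5
  s <- rep(0, 14)
  s[6] <- -2 # y3 < 0 -> H(Y3) = 0 -> I3 = 0
  d_neg <- heterogeneous_deriv(s, p)
  expect_identical(d_neg[11], 0) # dz3/dt
  s[6] <- 2 # Y3 = 2 -> I3 = C3 * 2 = 1.8e-4, scaled by k3 in dz3/dt
  d_pos <- heterogeneous_deriv(s, p)
  k3 <- p$muscles$QRS$k
  expect_equal(d_pos[11], k3 * 1.8e-4, tolerance = 1e-12)
  # all four channels obey I_j = C_j Y_j H(Y_j)
  for (y1 in c(-0.7, 0, 0.4)) {
    for (y3 in c(-1.2, 0, 0.9)) {
      s <- rep(0, 14); s[2] <- y1; s[6] <- y3
      d <- heterogeneous_deriv(s, p)
      Y <- c(y1, -y1, y3, -y3)
      Cj <- vapply(p$muscles, `[[`, numeric(1), "C")
      kj <- vapply(p$muscles, `[[`, numeric(1), "k")
      expect_equal(d[c(7, 9, 11, 13)],
                   unname(kj * ifelse(Y > 0, Cj * Y, 0)), tolerance = 1e-14)
    }
  }
})

test_that("heterogeneous coupling uses delayed upstream velocity", {
  p <- het_normal()
  s <- rep(0, 14)
  d0 <- heterogeneous_deriv(s, p, delayed = c(AV = 0, HP = 0))
  d1 <- heterogeneous_deriv(s, p, delayed = c(AV = 0.5, HP = 0))
  expect_equal(d1[4] - d0[4], p$pacemakers$AV$K * 0.5)
  expect_identical(d1[-4], d0[-4])
  expect_error(heterogeneous_deriv(s, p, delayed = c(AV = 0)), "HP")
  expect_error(heterogeneous_deriv(rep(0, 13), p), "length 14")
  expect_error(heterogeneous_deriv(c(rep(0, 13), NaN), p), "finite")
})

test_that("heterogeneous composition follows the signed weight pattern", {
  p <- het_normal()
  s <- rep(0, 14)
  expect_equal(compose_ecg_heterogeneous(s, p, "II"), 0.2) # z0 survives
  # alpha = (1,1,1,1), z = (1,1,1,1), z0 = 0 -> 1 - 1 + 1 + 1 = 2
  p2 <- p
  p2$lead_weights <- tibble::tibble(channel = "X", a1 = 1, a2 = 1, a3 = 1,
                                    a4 = 1, z0 = 0)
  s[c(7, 9, 11, 13)] <- 1
  expect_equal(compose_ecg_heterogeneous(s, p2, "X"), 2)
  # linearity in the muscle states
  s2 <- s; s2[c(7, 9, 11, 13)] <- c(0.3, -0.2, 1.4, 0.5)
  expect_equal(compose_ecg_heterogeneous(2 * s2, p2, "X"),
               2 * compose_ecg_heterogeneous(s2, p2, "X"))
  expect_error(compose_ecg_heterogeneous(s, p, "nope"), "available")
})

test_that("reaction-diffusion derivatives match term-by-term arithmetic", {
  p <- rd_normal() # H = 3, C = 1.35, beta = 4
  expect_identical(rd_deriv(rep(0, 4), p), rep(0, 4))
  expect_equal(rd_deriv(c(1, 0, 0, 0), p), c(1, 3, 0, 0))
  expect_equal(rd_deriv(c(0, 1, 0, 0), p), c(-1, -7, 0, 8))
  expect_error(rd_deriv(c(0, Inf, 0, 0), p), "finite")
})

test_that("reaction-diffusion composition is the K-weighted mixture", {
  p <- rd_normal()
  expect_equal(compose_ecg_rd(c(1, 1, 1, 1), p), sum(p$K))
  expect_equal(compose_ecg_rd(c(1, 1, 1, 1), p), 0.1164, tolerance = 1e-12)
  expect_equal(compose_ecg_rd(rep(0, 4), p), 0)
  p2 <- p; p2$K <- c(1, 0, 0, 0)
  x <- c(0.7, -2, 3.1, 0.2)
  expect_equal(compose_ecg_rd(x, p2), x[1])
})

test_that("ring derivatives: fixed points, couplings, and drives", {
  p <- ring_normal()
  # uncoupled, undriven, at the cubic root x = d with zero velocity
  p0 <- p
  p0$k <- as.list(setNames(rep(0, 6), ring_coupling_names()))
  for (nm in c("SA", "AV", "HP")) p0$nodes[[nm]]$rho <- 0
  s <- rep(0, 6)
  s[c(1, 3, 5)] <- vapply(p0$nodes, `[[`, numeric(1), "d")
  expect_equal(ring_deriv(s, t = 0.3, p0), rep(0, 6))

  # difference coupling vanishes when the delayed partner position agrees:
  # AV_SA couples node AV to the delayed SA position, so supplying
  # x1(t - tau) = x3 makes k (x3 - x1_del) vanish
  p1 <- p0
  p1$k$AV_SA <- 5
  s1 <- c(0.4, 0, 0.7, 0, -0.1, 0)
  del2 <- setNames(rep(0, 6), ring_coupling_names())
  del2["AV_SA"] <- s1[3]
  d_base <- ring_deriv(s1, 0, p0)
  d_coup <- ring_deriv(s1, 0, p1, delayed = del2)
  expect_equal(d_coup, d_base, tolerance = 1e-14)

  # missing delayed value for an active coupling is a contract violation
  expect_error(ring_deriv(s1, 0, p1, delayed = del2[0]), "AV_SA")

  # additive drive contributes exactly rho at sin = 1
  pvf <- get_preset("ring", "ventricular_fibrillation")$params
  om_eff <- pvf$nodes$SA$omega /
    sqrt(abs(pvf$nodes$SA$d * pvf$nodes$SA$e))
  t_star <- (pi / 2) / om_eff # sin(omega_eff * t) = 1
  del_all <- setNames(rep(0, 6), ring_coupling_names())
  s0 <- rep(0, 6)
  d_drive <- ring_deriv(s0, t_star, pvf, delayed = del_all)
  pvf0 <- pvf; pvf0$nodes$SA$rho <- 0
  d_nodrive <- ring_deriv(s0, t_star, pvf0, delayed = del_all)
  expect_equal(d_drive[2] - d_nodrive[2], pvf$nodes$SA$rho, tolerance = 1e-9)
})

test_that("ring composition is affine with the beta_G scale", {
  p <- ring_normal()
  expect_equal(compose_ecg_ring(rep(0, 6), p), p$alpha[1] * p$beta_G)
  p1 <- p; p1$alpha <- c(1, 0.1, 0.05, 0.4); p1$beta_G <- 0.0012
  expect_equal(compose_ecg_ring(rep(0, 6), p1), 0.0012)
  p0 <- p; p0$beta_G <- 1e-300 # beta_G must be nonzero; annihilation limit
  s <- stats::rnorm(6)
  expect_equal(compose_ecg_ring(s, p0) / 1e-300,
               compose_ecg_ring(s, p1) / 0.0012, tolerance = 1e-12)
  # affine in each state coordinate (finite differences are constant)
  base <- compose_ecg_ring(rep(0, 6), p)
  for (i in 1:6) {
    e_i <- rep(0, 6); e_i[i] <- 1
    d1 <- compose_ecg_ring(e_i, p) - base
    d2 <- (compose_ecg_ring(2 * e_i, p) - base) / 2
    expect_equal(d1, d2, tolerance = 1e-12)
  }
})

test_that("quasi-periodic kernels push-pull oddly around their centers", {
  p <- qp_normal()
  # at theta = theta_R the R kernel's own contribution vanishes: compare
  # a single-kernel system at its center
  ps <- qp_single_kernel(a = 30, b = 0.1, theta = 0.4)
  s <- c(cos(0.4), sin(0.4), 0, 0, 0)
  d <- qp_deriv(s, t = 0, ps)
  expect_equal(d[4], 0, tolerance = 1e-12) # C channel: only R active, dtheta = 0

  # all amplitudes zero and channels at baseline -> channel derivatives 0
  p0 <- p
  for (nm in names(p0$kernels)) p0$kernels[[nm]]$a <- 0
  s0 <- c(1, 0, baseline_wander(0.3, p0), baseline_wander(0.3, p0),
          baseline_wander(0.3, p0))
  expect_equal(qp_deriv(s0, t = 0.3, p0)[3:5], rep(0, 3), tolerance = 1e-15)

  # kernel antisymmetry: mirrored kernel pair with equal (a, b) cancels
  kern <- function(a, b, th, dth_from) {
    d <- wrap_angle(dth_from - th)
    -a * d * exp(-d^2 / (2 * b^2))
  }
  for (th0 in c(0, 0.7, -2)) {
    for (off in c(0.1, 0.5, 1)) {
      expect_equal(kern(2, 0.3, th0 - off, th0) + kern(2, 0.3, th0 + off, th0),
                   0, tolerance = 1e-15)
    }
  }
})

test_that("angle wrapping stays in [-pi, pi) and is continuous off the antipode", {
  th <- seq(-10, 10, by = 0.01)
  w <- wrap_angle(th)
  expect_true(all(w >= -pi & w < pi))
  # continuity: small increments wrap to small increments except at the cut
  dw <- diff(wrap_angle(seq(0.5, 0.5 + 4 * pi, by = 1e-3)))
  jumps <- sum(abs(dw) > 1)
  expect_equal(jumps, 2) # exactly one cut crossing per revolution
  expect_equal(wrap_angle(pi), -pi)
  expect_equal(wrap_angle(-pi), -pi)
  expect_equal(wrap_angle(3 * pi / 2), -pi / 2, tolerance = 1e-15)
})

test_that("baseline wander is the respiratory sinusoid", {
  p <- qp_normal() # A = 0.005, fr = 0.25
  expect_identical(baseline_wander(0, p), 0)
  expect_equal(baseline_wander(1 / (4 * p$fr), p), p$A)
  p0 <- p; p0$A <- 0
  expect_identical(baseline_wander(seq(0, 10, 0.1), p0), rep(0, 101))
})

test_that("quasi-periodic composition is the symmetric channel sum", {
  expect_equal(compose_ecg_qp(c(1, 0, 0, 0, 0)), 0)
  expect_equal(compose_ecg_qp(c(0.2, 0.1, 0.1, 1.0, 0.2)), 1.3)
  expect_equal(compose_ecg_qp(c(0.2, 0.1, 0.2, 0.1, 1.0)), 1.3)
})

test_that("all four composition maps are linear over their state arguments", {
  set.seed(42)
  hp <- het_normal(); rp <- rd_normal(); gp <- ring_normal()
  for (rep_i in 1:5) {
    lin_check <- function(f, d) {
      s1 <- stats::rnorm(d); s2 <- stats::rnorm(d)
      f0 <- f(rep(0, d))
      expect_equal((f(s1 + s2) - f0),
                   (f(s1) - f0) + (f(s2) - f0), tolerance = 1e-12)
    }
    lin_check(function(s) compose_ecg_heterogeneous(s, hp, "II"), 14)
    lin_check(function(s) compose_ecg_rd(s, rp), 4)
    lin_check(function(s) compose_ecg_ring(s, gp), 6)
    lin_check(compose_ecg_qp, 5)
  }
})
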