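# Right-hand sides of the four dynamical models and the linear compositions
# mapping state trajectories to ECG waveforms. These are the reference R
# implementations; integrate_model() runs an equivalent compiled core.

check_state <- function(state, model) {
  d <- model_dim(model)
  if (!is.numeric(state) || length(state) != d) {
    abort(paste0("state for '", model, "' must be numeric of length ", d))
  }
  if (!all(is.finite(state))) abort("state contains non-finite values")
  invisible(state)
}

as_state_matrix <- function(state, model) {
  d <- model_dim(model)
  if (is.matrix(state)) {
    if (ncol(state) != d) abort(paste0("trajectory must have ", d, " columns"))
    state
  } else {
    matrix(check_state(state, model), nrow = 1)
  }
}

#' Heterogeneous model derivatives
#'
#' Evaluates the 14 time derivatives of the heterogeneous conduction-system
#' model: three delayed-cascade Van der Pol pacemakers (SA, AV, HP) followed by
#' four FitzHugh-Nagumo muscle channels (P, Ta, QRS, T). State layout:
#' `c(x1, y1, x2, y2, x3, y3, z1, v1, z2, v2, z3, v3, z4, v4)`.
#'
#' The stimulation currents gate on the pacemaker velocities through the unit
#' step \eqn{H} (with \eqn{H(0) = 0}): \eqn{I_j = C_j Y_j H(Y_j)} with
#' \eqn{Y_1 = y_1}, \eqn{Y_2 = -y_1}, \eqn{Y_3 = y_3}, \eqn{Y_4 = -y_3}.
#'
#' @param state Numeric length-14 state vector.
#' @param params A [het_params()] object.
#' @param delayed Named numeric with the delayed upstream velocities seen by
#'   the coupled pacemakers: `AV` = \eqn{y_{SA}(t - \tau_{SA-AV})},
#'   `HP` = \eqn{y_{AV}(t - \tau_{AV-HP})}.
#' @return Numeric length-14 derivative vector.
#' @export
heterogeneous_deriv <- function(state, params,
                                delayed = c(AV = 0, HP = 0)) {
  check_state(state, "heterogeneous")
  if (!all(c("AV", "HP") %in% names(delayed))) {
    abort("`delayed` must supply named values for AV and HP")
  }
  pc <- params$pacemakers
  ds <- numeric(14)
  ydel <- c(SA = 0, AV = unname(delayed[["AV"]]), HP = unname(delayed[["HP"]]))
  for (i in seq_len(3)) {
    nm <- c("SA", "AV", "HP")[i]
    p <- pc[[nm]]
    x <- state[2 * i - 1]; y <- state[2 * i]
    coup <- if (nm == "SA") 0 else p$K * (ydel[[nm]] - y)
    ds[2 * i - 1] <- y
    ds[2 * i] <- -p$a * (x^2 - p$u) * y - p$f * x * (x + p$d) * (x + p$e) + coup
  }
  y1 <- state[2]; y3 <- state[6]
  Y <- c(y1, -y1, y3, -y3)
  mus <- params$muscles
  for (j in seq_len(4)) {
    m <- mus[[j]]
    z <- state[5 + 2 * j]; v <- state[6 + 2 * j]
    I <- if (Y[j] > 0) m$C * Y[j] else 0
    ds[5 + 2 * j] <- m$k * (-m$c * z * (z - m$w1) * (z - m$w2) - m$b * v -
                              m$g * v * z + I)
    ds[6 + 2 * j] <- m$k * m$h * (z - v)
  }
  ds
}

#' Compose an ECG channel from the heterogeneous model
#'
#' Linear composition of the four muscle responses into one lead channel:
#' \eqn{z_0 + \alpha_1 z_1 - \alpha_2 z_2 + \alpha_3 z_3 + \alpha_4 z_4}, using
#' the channel's row of `params$lead_weights`.
#'
#' @param state Length-14 state vector or a trajectory matrix (rows = time).
#' @param params A [het_params()] object.
#' @param channel Lead channel name present in `params$lead_weights`.
#' @return Potential value(s), one per state row.
#' @export
compose_ecg_heterogeneous <- function(state, params, channel = "II") {
  lw <- params$lead_weights
  row <- lw[lw$channel == channel, ]
  if (nrow(row) != 1L) {
    abort(paste0(
      "unknown lead channel '", channel, "'; available: ",
      paste(lw$channel, collapse = ", ")
    ))
  }
  s <- as_state_matrix(state, "heterogeneous")
  z <- s[, c(7, 9, 11, 13), drop = FALSE]
  row$z0 + row$a1 * z[, 1] - row$a2 * z[, 2] + row$a3 * z[, 3] + row$a4 * z[, 4]
}

#' Reaction-diffusion model derivatives
#'
#' Evaluates the four derivatives of the spatially discretized BVAM system,
#' including the asymmetric couplings \eqn{\beta (x_4 - x_2)} and
#' \eqn{2\beta (x_2 - x_4)}.
#'
#' @param state Numeric length-4 state vector.
#' @param params An [rd_params()] object.
#' @return Numeric length-4 derivative vector.
#' @export
rd_deriv <- function(state, params) {
  check_state(state, "reaction_diffusion")
  x1 <- state[1]; x2 <- state[2]; x3 <- state[3]; x4 <- state[4]
  H <- params$H; C <- params$C; b <- params$beta
  c(
    x1 - x2 - C * x1 * x2 - x1 * x2^2,
    H * x1 - 3 * x2 + C * x1 * x2 + x1 * x2^2 + b * (x4 - x2),
    x3 - x4 - C * x3 * x4 - x3 * x4^2,
    H * x3 - 3 * x4 + C * x3 * x4 + x3 * x4^2 + 2 * b * (x2 - x4)
  )
}

#' Compose the ECG read-out of the reaction-diffusion model
#'
#' @param state Length-4 state vector or trajectory matrix.
#' @param params An [rd_params()] object; uses the mixing weights `K`.
#' @return Potential value(s) \eqn{K_1 x_1 + K_2 x_2 + K_3 x_3 + K_4 x_4}.
#' @export
compose_ecg_rd <- function(state, params) {
  s <- as_state_matrix(state, "reaction_diffusion")
  drop(s %*% params$K)
}

#' Ring model derivatives
#'
#' Evaluates the six derivatives of the ring of three delay-coupled modified
#' Van der Pol oscillators. State layout: `c(x1, x2, x3, x4, x5, x6)` with
#' positions `x1` (SA), `x3` (AV), `x5` (HP) and their velocities. Each
#' velocity equation carries a sinusoidal drive \eqn{\rho \sin(\omega t)}
#' (entering additively), the normalized restoring cubic of [ring_params()],
#' and delayed difference couplings
#' \eqn{-k_{X-Y} (x_X - x_Y(t - \tau_{X-Y}))}.
#'
#' @param state Numeric length-6 state vector.
#' @param t Model time (enters the sinusoidal drives).
#' @param params A [ring_params()] object.
#' @param delayed Named numeric of delayed partner positions, one per directed
#'   coupling (`SA_AV`, `SA_HP`, `AV_SA`, `AV_HP`, `HP_SA`, `HP_AV`). Entries
#'   may be omitted only for couplings with zero constant.
#' @return Numeric length-6 derivative vector.
#' @export
ring_deriv <- function(state, t, params, delayed = NULL) {
  check_state(state, "ring")
  cn <- ring_coupling_names()
  kv <- unlist(params$k[cn])
  if (is.null(delayed)) delayed <- setNames(numeric(6), cn)
  missing <- cn[kv != 0 & !cn %in% names(delayed)]
  if (length(missing)) {
    abort(paste0("missing delayed value(s) for nonzero coupling(s): ",
                 paste(missing, collapse = ", ")))
  }
  del <- setNames(numeric(6), cn)
  del[names(delayed)] <- delayed
  pos <- state[c(1, 3, 5)]
  ds <- numeric(6)
  node_names <- c("SA", "AV", "HP")
  # couplings entering node X's velocity equation, in (partner, name) pairs
  coup_map <- list(
    SA = c("SA_AV", "SA_HP"),
    AV = c("AV_SA", "AV_HP"),
    HP = c("HP_SA", "HP_AV")
  )
  for (i in seq_len(3)) {
    nm <- node_names[i]
    nd <- params$nodes[[nm]]
    x <- state[2 * i - 1]; v <- state[2 * i]
    coup <- 0
    for (cnm in coup_map[[nm]]) {
      coup <- coup + kv[[cnm]] * (x - del[[cnm]])
    }
    ds[2 * i - 1] <- v
    # restoring cubic normalized by d*e (small-amplitude frequency ~1 rad
    # per model time unit); the tabulated drive frequency, expressed in the
    # un-normalized time base, is converted by the same sqrt(|d*e|) factor
    ds[2 * i] <- -nd$a * v * (x - nd$w1) * (x - nd$w2) +
      nd$rho * sin(nd$omega / sqrt(abs(nd$d * nd$e)) * t) -
      x * (x - nd$d) * (x - nd$e) / (nd$d * nd$e) - coup
  }
  ds
}

#' Compose the ECG read-out of the ring model
#'
#' @param state Length-6 state vector or trajectory matrix.
#' @param params A [ring_params()] object.
#' @return Potential value(s)
#'   \eqn{(\alpha_0 + \alpha_1 x_1 + \alpha_3 x_3 + \alpha_5 x_5) \beta_G}.
#' @export
compose_ecg_ring <- function(state, params) {
  s <- as_state_matrix(state, "ring")
  a <- params$alpha
  (a[1] + a[2] * s[, 1] + a[3] * s[, 3] + a[4] * s[, 5]) * params$beta_G
}

#' Wrap an angle difference to \[-pi, pi)
#'
#' @param x Angle(s) in radians.
#' @return Wrapped angle(s) in \eqn{[-\pi, \pi)}.
#' @export
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi)
  w - pi
}

qp_amplitudes <- function(params) {
  a <- vapply(params$kernels[qp_kernel_names()], `[[`, numeric(1), "a")
  if (params$a_transform) {
    b <- vapply(params$kernels[qp_kernel_names()], `[[`, numeric(1), "b")
    a <- a * b^2
  }
  a
}

#' Quasi-periodic model derivatives
#'
#' Evaluates the five derivatives of the quasi-periodic Gaussian-kernel model.
#' State layout: `c(x, y, P, C, T)`. The planar subsystem has an attracting
#' unit limit cycle, \eqn{\dot x = \alpha x - \omega y},
#' \eqn{\dot y = \alpha y + \omega x} with \eqn{\alpha = 1 - \sqrt{x^2 + y^2}},
#' so on the unit circle the motion is a pure rotation at \eqn{\omega}. Each
#' waveform channel accumulates the push-pull of its kernels at the current
#' trajectory angle \eqn{\theta = \mathrm{atan2}(y, x)} and relaxes to the
#' respiratory baseline of [baseline_wander()].
#'
#' @param state Numeric length-5 state vector.
#' @param t Model time.
#' @param params A [qp_params()] object.
#' @param omega Angular frequency override (rad per model time unit); defaults
#'   to `2 * pi * params$hr / 60`.
#' @return Numeric length-5 derivative vector.
#' @export
qp_deriv <- function(state, t, params, omega = NULL) {
  check_state(state, "quasi_periodic")
  if (is.null(omega)) omega <- 2 * pi * params$hr / 60
  x <- state[1]; y <- state[2]
  r <- sqrt(x^2 + y^2)
  al <- 1 - r
  theta <- atan2(y, x)
  a <- qp_amplitudes(params)
  b <- vapply(params$kernels[qp_kernel_names()], `[[`, numeric(1), "b")
  th <- vapply(params$kernels[qp_kernel_names()], `[[`, numeric(1), "theta")
  dth <- wrap_angle(theta - th)
  push <- a * dth * exp(-dth^2 / (2 * b^2))
  z0 <- baseline_wander(t, params)
  groups <- list(P = 1:2, C = 3:5, T = 6:7)
  c(
    al * x - omega * y,
    al * y + omega * x,
    -sum(push[groups$P]) - (state[3] - z0),
    -sum(push[groups$C]) - (state[4] - z0),
    -sum(push[groups$T]) - (state[5] - z0)
  )
}

#' Respiratory baseline wander
#'
#' The common baseline of the three waveform channels of the quasi-periodic
#' model, coupled to the respiratory frequency:
#' \eqn{P_0(t) = C_0(t) = T_0(t) = A \sin(2\pi f_r t)}.
#'
#' @param t Model time (vectorized).
#' @param params A [qp_params()] object (fields `A`, `fr`).
#' @return Baseline value(s).
#' @export
baseline_wander <- function(t, params) {
  params$A * sin(2 * pi * params$fr * t)
}

#' Compose the ECG read-out of the quasi-periodic model
#'
#' @param state Length-5 state vector or trajectory matrix.
#' @return Potential value(s) \eqn{P + C + T}.
#' @export
compose_ecg_qp <- function(state) {
  s <- as_state_matrix(state, "quasi_periodic")
  s[, 3] + s[, 4] + s[, 5]
}
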