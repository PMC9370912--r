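# Fixed-step RK4 integration of the four models, with ring-buffer evaluation
# of time-delayed couplings. integrate_model() runs the compiled cores in
# src/integrators.cpp; rk4_step(), delay_buffer() and integrate_reference()
# are the equivalent R-level primitives (and the in-suite cross-check).

#' One classical fourth-order Runge-Kutta step
#'
#' Advances a state vector by one step of the classical RK4 scheme. Any
#' time-delayed quantities must be resolved by the caller before the step and
#' passed through `...`: they are held frozen across the four stage
#' evaluations, matching the sample-buffer strategy of the compiled
#' integrators.
#'
#' @param deriv Function `deriv(t, state, ...)` returning the derivative
#'   vector.
#' @param state Numeric state vector.
#' @param t Model time at the start of the step.
#' @param h Step size (> 0).
#' @param ... Passed on to `deriv` (e.g. frozen delayed values).
#' @return The state vector after one step.
#' @export
rk4_step <- function(deriv, state, t, h, ...) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0) abort("`h` must be > 0")
  k1 <- deriv(t, state, ...)
  k2 <- deriv(t + h / 2, state + h / 2 * k1, ...)
  k3 <- deriv(t + h / 2, state + h / 2 * k2, ...)
  k4 <- deriv(t + h, state + h * k3, ...)
  stages <- c(k1, k2, k3, k4)
  if (!all(is.finite(stages))) {
    abort(
      paste0(
        "non-finite RK4 stage value at t = ", format(t),
        "; state = [", paste(format(state), collapse = ", "), "]"
      ),
      class = "ecgsim_integration_error"
    )
  }
  state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Fixed-capacity history buffer for delayed couplings
#'
#' Creates a ring buffer holding past samples of one delayed quantity, sized
#' from the ratio of the largest transport delay to the integration step:
#' `capacity = max(1, ceiling(max_delay / step))`. Lookups before the start of
#' the integration return the constant pre-history value `init` (the standard
#' constant-history convention for delay differential equations).
#'
#' @param max_delay Largest delay that will be looked up (>= 0).
#' @param step Integration step in model time units (> 0).
#' @param init Constant history value for times before the first sample.
#' @return A `delay_buffer` object. Use [buffer_push()] once per accepted step
#'   and [delay_lookup()] to read delayed values.
#' @export
delay_buffer <- function(max_delay, step, init = 0) {
  if (max_delay < 0) abort("`max_delay` must be >= 0")
  if (step <= 0) abort("`step` must be > 0")
  capacity <- max(1L, as.integer(ceiling(max_delay / step)))
  env <- new.env(parent = emptyenv())
  env$step <- step
  env$capacity <- capacity
  env$init <- init
  env$store <- rep(init, capacity + 1L)
  env$n <- 0L # samples pushed so far; sample i (1-based) is at time (i-1)*step
  class(env) <- "delay_buffer"
  env
}

#' Record the current sample in a delay buffer
#'
#' @param buffer A [delay_buffer()].
#' @param value The value of the buffered quantity at the current step.
#' @return The buffer, invisibly.
#' @export
buffer_push <- function(buffer, value) {
  buffer$n <- buffer$n + 1L
  buffer$store[(buffer$n - 1L) %% (buffer$capacity + 1L) + 1L] <- value
  invisible(buffer)
}

#' Look up a delayed value from a buffer
#'
#' Returns the stored sample nearest to `now - tau`, with `tau / step` rounded
#' to the nearest integer sample offset. Lookups reaching before the first
#' stored sample return the buffer's constant history value.
#'
#' @param buffer A [delay_buffer()].
#' @param tau Delay (>= 0, at most `capacity * step`).
#' @param now Current model time (time of the most recent pushed sample).
#' @return The delayed value.
#' @export
delay_lookup <- function(buffer, tau, now) {
  if (tau < 0) abort("`tau` must be >= 0")
  offset <- as.integer(round(tau / buffer$step))
  if (offset > buffer$capacity) {
    abort(paste0(
      "delay ", format(tau), " exceeds buffer capacity (",
      buffer$capacity, " samples of ", format(buffer$step), ")"
    ))
  }
  idx <- buffer$n - offset # 1-based index of the wanted sample
  if (idx < 1L) return(buffer$init)
  buffer$store[(idx - 1L) %% (buffer$capacity + 1L) + 1L]
}

#' Default initial state of a model
#'
#' Pacemakers start slightly off their unstable rest point so the limit cycle
#' is reached quickly; the reaction-diffusion network starts at the asymmetric
#' unit kick `(1, 0, 0, 0)`, which lies in the basin of its large oscillatory
#' attractor (the origin's neighborhood is attracting along near-uniform
#' directions, so small symmetric perturbations die out); the quasi-periodic
#' model starts on its unit limit cycle at angle 0. The initial transient is
#' discarded at rendering time (see [render_trace()]).
#'
#' @param model Model identifier.
#' @return Named numeric state vector.
#' @export
default_initial_state <- function(model) {
  model <- check_model(model)
  switch(model,
    heterogeneous = setNames(
      c(rep(c(0.1, 0), 3), rep(0, 8)),
      c("x1", "y1", "x2", "y2", "x3", "y3",
        "z1", "v1", "z2", "v2", "z3", "v3", "z4", "v4")
    ),
    reaction_diffusion = setNames(c(1, 0, 0, 0), paste0("x", 1:4)),
    ring = setNames(rep(c(0.1, 0), 3), paste0("x", 1:6)),
    quasi_periodic = setNames(c(1, 0, 0, 0, 0), c("x", "y", "P", "C", "T"))
  )
}

state_names <- function(model) names(default_initial_state(model))

min_positive_delay <- function(model, params) {
  taus <- switch(model,
    heterogeneous = vapply(params$pacemakers, `[[`, numeric(1), "tau"),
    ring = unlist(params$tau),
    numeric(0)
  )
  taus <- taus[taus > 0]
  if (length(taus)) min(taus) else Inf
}

#' Integrate a heartbeat model
#'
#' Solves one of the four models with the fixed-step classical RK4 scheme.
#' Time-delayed couplings (heterogeneous and ring models) are evaluated from a
#' sample buffer at offset `round(tau / step)` and held frozen within each
#' step's four stages; pre-history is the constant initial state. The result is
#' the full trajectory at the integration step, in model time; use
#' [render_trace()] to obtain a calibrated ECG waveform in output time.
#'
#' Integration is deterministic: identical `(params, duration, step, init,
#' seed)` give bitwise-identical trajectories, including the stochastic
#' RR-tachogram mode of the quasi-periodic model under a fixed seed.
#'
#' @param model Model identifier: `"heterogeneous"`, `"reaction_diffusion"`,
#'   `"ring"`, or `"quasi_periodic"`.
#' @param params Matching parameter object ([het_params()], [rd_params()],
#'   [ring_params()], [qp_params()]).
#' @param duration Total model time to integrate (> 0).
#' @param step Integration step in model time units; default `1e-3` for every
#'   model. Must not exceed the smallest positive coupling delay.
#' @param init Initial state; defaults to [default_initial_state()].
#' @param seed Integer seed for the stochastic tachogram mode (ignored by the
#'   deterministic models).
#' @return An `ecg_trajectory` list with elements `model`, `params`, `time`,
#'   `state` (matrix with named columns), `step`, and for the tachogram mode
#'   `rr` (the beat-to-beat RR series used).
#' @export
integrate_model <- function(model, params, duration, step = 1e-3,
                            init = NULL, seed = NULL) {
  model <- check_model(model)
  stop_on_problems(validate_params(model, params))
  if (!is.numeric(duration) || duration <= 0) abort("`duration` must be > 0")
  if (!is.numeric(step) || step <= 0) abort("`step` must be > 0")
  if (step > min_positive_delay(model, params)) {
    abort("`step` must not exceed the smallest positive coupling delay")
  }
  if (is.null(init)) init <- default_initial_state(model)
  check_state(init, model)
  n <- n_steps(duration, step)

  rr <- NULL
  res <- switch(model,
    heterogeneous = {
      pac <- t(vapply(
        params$pacemakers[c("SA", "AV", "HP")],
        function(p) unlist(p[c("a", "u", "f", "d", "e", "K")]),
        numeric(6)
      ))
      off <- as.integer(round(vapply(
        params$pacemakers[c("SA", "AV", "HP")], `[[`, numeric(1), "tau"
      ) / step))
      mus <- t(vapply(
        params$muscles[c("P", "Ta", "QRS", "T")],
        function(m) unlist(m[c("k", "c", "w1", "w2", "b", "g", "h", "C")]),
        numeric(8)
      ))
      integrate_het_cpp(pac, off, mus, as.numeric(init), step, n)
    },
    reaction_diffusion = integrate_rd_cpp(
      params$H, params$C, params$beta, as.numeric(init), step, n
    ),
    ring = {
      nodes <- t(vapply(
        params$nodes[c("SA", "AV", "HP")],
        function(p) unlist(p[c("a", "w1", "w2", "d", "e", "rho", "omega")]),
        numeric(7)
      ))
      cn <- ring_coupling_names()
      kc <- as.numeric(unlist(params$k[cn]))
      off <- as.integer(round(as.numeric(unlist(params$tau[cn])) / step))
      integrate_ring_cpp(nodes, kc, off, as.numeric(init), step, n)
    },
    quasi_periodic = {
      kn <- qp_kernel_names()
      a <- qp_amplitudes(params)
      b <- vapply(params$kernels[kn], `[[`, numeric(1), "b")
      th <- vapply(params$kernels[kn], function(k) parse_angle(k$theta),
                   numeric(1))
      if (is.null(params$tachogram)) {
        omega <- 2 * pi * params$hr / 60
      } else {
        rr <- rr_tachogram(
          params$tachogram,
          n_beats = as.integer(ceiling(duration / 0.2)) + 5L,
          seed = seed
        )
        omega <- omega_steps_from_rr(rr, step, n)
      }
      integrate_qp_cpp(a, b, th, params$A, params$fr, omega,
                       as.numeric(init), step, n)
    }
  )

  if (!res$ok) {
    i_last <- res$i_fail - 1L
    last <- res$trajectory[i_last + 1L, ]
    abort(
      paste0(
        "integration of '", model, "' produced non-finite values at t = ",
        format(res$i_fail * step), "; last finite state at t = ",
        format(i_last * step), ": [",
        paste(format(last, digits = 4), collapse = ", "), "]"
      ),
      class = "ecgsim_integration_error"
    )
  }
  state <- res$trajectory
  colnames(state) <- state_names(model)
  out <- list(
    model = model, params = params,
    time = seq(0, by = step, length.out = n + 1L),
    state = state, step = step, seed = seed, rr = rr
  )
  class(out) <- "ecg_trajectory"
  out
}

#' @export
print.ecg_trajectory <- function(x, ...) {
  cat("<ecg_trajectory> model:", x$model,
      "| steps:", length(x$time) - 1L,
      "| step:", format(x$step),
      "| model-time span:", format(max(x$time)), "\n")
  invisible(x)
}

# per-step angular frequency vector for the tachogram mode: beat k occupies
# model time [cum_{k-1}, cum_k) and rotates at 2*pi / rr_k
omega_steps_from_rr <- function(rr, step, n) {
  ends <- cumsum(rr)
  if (ends[length(ends)] < n * step) {
    abort("RR series too short for requested duration")
  }
  t_steps <- (seq_len(n) - 1L) * step
  beat <- findInterval(t_steps, c(0, ends), rightmost.closed = FALSE)
  2 * pi / rr[pmin(beat, length(rr))]
}

# ---- pure-R reference integrator (cross-check of the compiled cores) -------

#' Reference R implementation of the model integrator
#'
#' A direct R-level mirror of [integrate_model()] built from [rk4_step()],
#' [delay_buffer()] and [delay_lookup()], sharing the exact delayed-sample
#' semantics of the compiled cores. Intended for verification and for stepping
#' through the method interactively; for production runs use
#' [integrate_model()], which is orders of magnitude faster.
#'
#' @inheritParams integrate_model
#' @return An `ecg_trajectory`, as for [integrate_model()]. The quasi-periodic
#'   model is supported in constant-frequency mode only.
#' @export
integrate_reference <- function(model, params, duration, step = 1e-3,
                                init = NULL) {
  model <- check_model(model)
  stop_on_problems(validate_params(model, params))
  if (is.null(init)) init <- default_initial_state(model)
  check_state(init, model)
  n <- n_steps(duration, step)
  state <- matrix(NA_real_, n + 1L, model_dim(model),
                  dimnames = list(NULL, state_names(model)))
  state[1, ] <- init
  s <- as.numeric(init)

  if (model == "heterogeneous") {
    tau <- vapply(params$pacemakers[c("SA", "AV", "HP")], `[[`, numeric(1), "tau")
    buf_y1 <- delay_buffer(max(tau), step, init = init[["y1"]])
    buf_y2 <- delay_buffer(max(tau), step, init = init[["y2"]])
    for (i in seq_len(n)) {
      now <- (i - 1L) * step
      buffer_push(buf_y1, s[2]); buffer_push(buf_y2, s[4])
      delayed <- c(
        AV = delay_lookup(buf_y1, tau[["AV"]], now),
        HP = delay_lookup(buf_y2, tau[["HP"]], now)
      )
      s <- rk4_step(
        function(t, st, ...) heterogeneous_deriv(st, params, delayed),
        s, now, step
      )
      state[i + 1L, ] <- s
    }
  } else if (model == "reaction_diffusion") {
    for (i in seq_len(n)) {
      s <- rk4_step(function(t, st) rd_deriv(st, params), s, (i - 1L) * step, step)
      state[i + 1L, ] <- s
    }
  } else if (model == "ring") {
    cn <- ring_coupling_names()
    taus <- unlist(params$tau[cn])
    pos_idx <- c(SA_AV = 3L, SA_HP = 5L, AV_SA = 1L, AV_HP = 5L,
                 HP_SA = 1L, HP_AV = 3L)
    bufs <- lapply(c(1L, 3L, 5L), function(j) {
      delay_buffer(max(taus), step, init = init[[j]])
    })
    names(bufs) <- c("1", "3", "5")
    for (i in seq_len(n)) {
      now <- (i - 1L) * step
      for (j in c(1L, 3L, 5L)) buffer_push(bufs[[as.character(j)]], s[j])
      delayed <- vapply(cn, function(nm) {
        delay_lookup(bufs[[as.character(pos_idx[[nm]])]], taus[[nm]], now)
      }, numeric(1))
      s <- rk4_step(
        function(t, st, ...) ring_deriv(st, t, params, delayed),
        s, now, step
      )
      state[i + 1L, ] <- s
    }
  } else { # quasi_periodic, constant omega
    for (i in seq_len(n)) {
      s <- rk4_step(function(t, st) qp_deriv(st, t, params), s, (i - 1L) * step, step)
      state[i + 1L, ] <- s
    }
  }

  out <- list(
    model = model, params = params,
    time = seq(0, by = step, length.out = n + 1L),
    state = state, step = step, seed = NULL, rr = NULL
  )
  class(out) <- "ecg_trajectory"
  out
}

# Dense-history oracle for the ring model: stores the full trajectory and
# resolves delayed positions by linear interpolation in time (rather than
# nearest-sample lookup). Used to bound the error of the buffered scheme.
ring_dense_oracle <- function(params, duration, step = 1e-3, init = NULL) {
  if (is.null(init)) init <- default_initial_state("ring")
  n <- n_steps(duration, step)
  state <- matrix(NA_real_, n + 1L, 6L,
                  dimnames = list(NULL, state_names("ring")))
  state[1, ] <- init
  s <- as.numeric(init)
  cn <- ring_coupling_names()
  taus <- unlist(params$tau[cn])
  pos_idx <- c(SA_AV = 3L, SA_HP = 5L, AV_SA = 1L, AV_HP = 5L,
               HP_SA = 1L, HP_AV = 3L)
  lookup <- function(i_now, tau, col) {
    if (tau == 0) return(state[i_now, col])
    t_past <- (i_now - 1L) * step - tau
    if (t_past <= 0) return(init[[col]])
    j <- floor(t_past / step) # sample j is at time j*step, row j+1
    frac <- t_past / step - j
    lo <- state[j + 1L, col]
    hi <- state[min(j + 2L, i_now), col]
    lo + frac * (hi - lo)
  }
  for (i in seq_len(n)) {
    now <- (i - 1L) * step
    delayed <- vapply(cn, function(nm) {
      lookup(i, taus[[nm]], pos_idx[[nm]])
    }, numeric(1))
    s <- rk4_step(
      function(t, st, ...) ring_deriv(st, t, params, delayed),
      s, now, step
    )
    state[i + 1L, ] <- s
  }
  out <- list(
    model = "ring", params = params,
    time = seq(0, by = step, length.out = n + 1L),
    state = state, step = step, seed = NULL, rr = NULL
  )
  class(out) <- "ecg_trajectory"
  out
}

# number of RK4 steps covering `duration`; tolerant of floating-point noise in
# duration/step so an exact multiple never gains a spurious extra step
n_steps <- function(duration, step) {
  as.integer(ceiling(duration / step - sqrt(.Machine$double.eps)))
}
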