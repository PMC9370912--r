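# Shared fixtures: small parameter sets built in code, plus a cache so the
# long preset integrations run once per test session.

.run_cache <- new.env(parent = emptyenv())

# integrate a shipped preset and return trajectory + pre-gain composition +
# rendered trace, memoised on (model, rhythm, duration)
run_preset <- function(model, rhythm, duration = 30, seed = 1L) {
  key <- paste(model, rhythm, duration, seed, sep = "|")
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  preset <- get_preset(model, rhythm)
  transient <- min(5, duration / 4)
  model_dur <- (duration + transient) * preset$time_scale
  traj <- integrate_model(model, preset$params, model_dur, seed = seed)
  composed <- switch(model,
    heterogeneous = compose_ecg_heterogeneous(traj$state, preset$params, "II"),
    reaction_diffusion = compose_ecg_rd(traj$state, preset$params),
    ring = compose_ecg_ring(traj$state, preset$params),
    quasi_periodic = compose_ecg_qp(traj$state)
  )
  trace <- render_trace(traj, time_scale = preset$time_scale,
                        gain = preset$gain, transient = transient)
  out <- list(preset = preset, trajectory = traj, composed = composed,
              trace = trace)
  .run_cache[[key]] <- out
  out
}

# a minimal valid quasi-periodic parameter set with a single R kernel
qp_single_kernel <- function(a = 30, b = 0.1, theta = 0, hr = 60) {
  kern <- list(
    Pminus = gaussian_kernel(0, 0.2, -1), Pplus = gaussian_kernel(0, 0.2, -1),
    Q = gaussian_kernel(0, 0.1, -0.2), R = gaussian_kernel(a, b, theta),
    S = gaussian_kernel(0, 0.1, 0.2),
    Tminus = gaussian_kernel(0, 0.3, 1.5), Tplus = gaussian_kernel(0, 0.3, 1.5)
  )
  qp_params(kernels = kern, hr = hr, A = 0)
}

# random ground-referenced electrode potentials
random_electrodes <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    RA = stats::runif(n, -2, 2),
    LA = stats::runif(n, -2, 2),
    LL = stats::runif(n, -2, 2)
  )
}

# elementwise units-in-the-last-place style bound
ulp_bound <- function(..., n_ulps = 4) {
  mags <- do.call(pmax, c(lapply(list(...), abs), list(1)))
  n_ulps * .Machine$double.eps * mags
}

# synthetic impulse train: sharp triangular peaks at a given rate
impulse_train <- function(rate_hz, duration, fs = 500, jitter = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = 1 / fs)
  v <- numeric(length(t))
  centers <- seq(0.5, duration - 0.5, by = 1 / rate_hz)
  if (jitter > 0) centers <- centers + stats::runif(length(centers), -jitter, jitter)
  for (ct in centers) {
    idx <- which(abs(t - ct) < 0.02)
    v[idx] <- pmax(v[idx], 1 - abs(t[idx] - ct) / 0.02)
  }
  list(t = t, v = v, fs = fs)
}
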