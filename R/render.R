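# Turns model-time trajectories into calibrated, uniformly sampled ECG tibbles.

#' Construct an ECG tibble
#'
#' An `ecg_tbl` is a tibble with a `time` column (seconds) and one numeric
#' column per channel (millivolts), plus attributes `fs` (sampling rate, Hz),
#' `units`, and optionally `model` and `rhythm`.
#'
#' @param time Numeric time vector (seconds), uniformly spaced.
#' @param channels Named list/data frame of equal-length channel vectors.
#' @param fs Sampling rate in Hz.
#' @param model,rhythm Optional provenance strings.
#' @return An `ecg_tbl`.
#' @export
ecg_tbl <- function(time, channels, fs, model = NULL, rhythm = NULL) {
  stopifnot(is.numeric(time), fs > 0)
  channels <- as.list(channels)
  lens <- lengths(channels)
  if (length(lens) == 0) abort("at least one channel is required")
  if (any(lens != length(time))) abort("all channels must match `time` length")
  out <- tibble::tibble(time = time, !!!channels)
  class(out) <- c("ecg_tbl", class(out))
  attr(out, "fs") <- fs
  attr(out, "units") <- "mV"
  attr(out, "model") <- model
  attr(out, "rhythm") <- rhythm
  out
}

#' Channel names of an ECG tibble
#' @param x An `ecg_tbl`.
#' @return Character vector of channel column names.
#' @export
ecg_channels <- function(x) setdiff(names(x), "time")

#' Sampling rate of an ECG tibble
#' @param x An `ecg_tbl` (or data frame with a uniform `time` column).
#' @return Sampling rate in Hz.
#' @export
ecg_fs <- function(x) {
  fs <- attr(x, "fs")
  if (!is.null(fs)) return(fs)
  dt <- median(diff(x$time))
  1 / dt
}

default_transient <- function(duration_out) min(5, duration_out / 4)

#' Render an ECG trace from a model trajectory
#'
#' Applies a composition map pointwise to a trajectory, converts model time to
#' output time (dividing by `time_scale`, so larger factors give faster
#' rhythms), discards the initial transient, resamples by linear interpolation
#' onto a uniform grid at `fs`, and calibrates the amplitude so that the
#' detected R-peak magnitude (largest excursion from the median baseline)
#' equals `gain` millivolts. A flat composed signal cannot be calibrated and
#' falls back to unit scale with a warning.
#'
#' @param trajectory An `ecg_trajectory` from [integrate_model()].
#' @param compose Composition: a channel name for the heterogeneous model, or
#'   a function `f(state_matrix)` returning one value per row. `NULL` picks
#'   the model's standard single-lead (lead II) composition.
#' @param time_scale Time-compression factor; `NULL` takes `Gamma_t` /
#'   `beta_T` from the parameters (1 for the other models).
#' @param gain Target R-peak amplitude in mV.
#' @param fs Output sampling rate in Hz.
#' @param transient Output-time seconds to discard from the start of the run;
#'   default is 20% of the rendered span, capped at 5 s.
#' @param channel_name Name for the output channel column.
#' @return A single-channel [ecg_tbl()].
#' @export
render_trace <- function(trajectory, compose = NULL, time_scale = NULL,
                         gain = 1, fs = 500, transient = NULL,
                         channel_name = NULL) {
  stopifnot(inherits(trajectory, "ecg_trajectory"))
  if (fs <= 0) abort("`fs` must be > 0")
  model <- trajectory$model
  params <- trajectory$params
  if (is.null(time_scale)) {
    time_scale <- switch(model,
      reaction_diffusion = params$Gamma_t,
      ring = params$beta_T,
      1
    )
  }
  if (is.null(compose)) {
    compose <- switch(model,
      heterogeneous = "II",
      reaction_diffusion = function(s) compose_ecg_rd(s, params),
      ring = function(s) compose_ecg_ring(s, params),
      quasi_periodic = function(s) compose_ecg_qp(s)
    )
  }
  if (is.character(compose)) {
    ch <- compose
    compose <- function(s) compose_ecg_heterogeneous(s, params, ch)
    if (is.null(channel_name)) channel_name <- ch
  }
  if (is.null(channel_name)) channel_name <- "ECG"

  v <- compose(trajectory$state)
  t_out <- trajectory$time / time_scale
  span <- max(t_out)
  if (is.null(transient)) transient <- default_transient(span)
  if (transient >= span) abort("transient longer than the rendered span")

  grid <- seq(transient, span, by = 1 / fs)
  vi <- approx(t_out, v, xout = grid)$y
  vc <- vi - median(vi)
  peak <- max(abs(vc))
  if (peak == 0) {
    warn("flat composed signal; gain calibration falls back to unit scale")
    scale <- 1
  } else {
    scale <- gain / peak
  }
  ecg_tbl(
    time = (seq_along(grid) - 1) / fs,
    channels = setNames(list(vc * scale), channel_name),
    fs = fs, model = model
  )
}
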