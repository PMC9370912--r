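# One-call simulation entry points built on presets + integrator + renderer.

#' Simulate a single-lead ECG from a rhythm preset
#'
#' Retrieves the requested preset, integrates its model for long enough to
#' cover the requested output duration plus the discarded start-up transient,
#' and renders a calibrated lead-II trace (the standard Einthoven lead II is
#' the single lead the reaction-diffusion, ring and quasi-periodic models
#' reproduce; for the heterogeneous model any weighted channel may be chosen).
#'
#' @param model Model identifier.
#' @param rhythm Preset rhythm name (see [list_presets()]).
#' @param duration Output duration in seconds.
#' @param fs Output sampling rate (Hz).
#' @param gain Target R-peak amplitude in mV; `NULL` keeps the preset's gain.
#' @param seed Integer seed for stochastic components (RR tachogram).
#' @param step Integration step in model time units.
#' @param overrides Named list of dotted-path parameter overrides, as in
#'   [get_preset()].
#' @param channel Lead channel for the heterogeneous model (default `"II"`).
#' @return A single-channel [ecg_tbl()] of `duration` seconds at `fs` Hz.
#' @examples
#' ecg <- simulate_ecg("quasi_periodic", "normal", duration = 10, seed = 1)
#' estimate_beat_rate(ecg)
#' @export
simulate_ecg <- function(model, rhythm, duration = 10, fs = 500, gain = NULL,
                         seed = 1L, step = 1e-3, overrides = NULL,
                         channel = "II") {
  preset <- get_preset(model, rhythm, overrides = overrides, gain = gain)
  transient <- min(5, duration / 4)
  model_dur <- (duration + transient) * preset$time_scale
  traj <- integrate_model(preset$model, preset$params, model_dur,
                          step = step, seed = seed)
  trace <- render_trace(
    traj,
    compose = if (preset$model == "heterogeneous") channel else NULL,
    time_scale = preset$time_scale, gain = preset$gain, fs = fs,
    transient = transient,
    channel_name = if (preset$model == "heterogeneous") channel else "II"
  )
  trace <- trace[trace$time < duration + 0.5 / fs, ]
  attr(trace, "rhythm") <- preset$rhythm
  attr(trace, "fs") <- fs
  class(trace) <- c("ecg_tbl", class(tibble()))
  trace
}

#' Simulate a full 12-lead ECG profile
#'
#' Runs the heterogeneous conduction-system model (the one model that
#' reproduces a realistic 12-lead profile) for the requested rhythm and
#' assembles the 12 standard channels via [twelve_lead_profile()].
#'
#' @inheritParams simulate_ecg
#' @param rhythm Heterogeneous-model rhythm (`"normal"`,
#'   `"complete_SA_AV_block"`, `"complete_AV_HP_block"`).
#' @return A 12-channel [ecg_tbl()].
#' @export
simulate_leads12 <- function(rhythm = "normal", duration = 10, fs = 500,
                             gain = NULL, seed = 1L, step = 1e-3,
                             overrides = NULL) {
  preset <- get_preset("heterogeneous", rhythm, overrides = overrides,
                       gain = gain)
  transient <- min(5, duration / 4)
  model_dur <- (duration + transient) * preset$time_scale
  traj <- integrate_model("heterogeneous", preset$params, model_dur,
                          step = step, seed = seed)
  leads <- twelve_lead_profile(traj, preset$params, fs = fs,
                               gain = preset$gain, transient = transient,
                               time_scale = preset$time_scale)
  leads <- leads[leads$time < duration + 0.5 / fs, ]
  attr(leads, "rhythm") <- preset$rhythm
  attr(leads, "fs") <- fs
  class(leads) <- c("ecg_tbl", class(tibble()))
  leads
}
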