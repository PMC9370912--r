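# broom-style tidiers for simulation results and presets.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ECG tibble into long format
#'
#' @param x An [ecg_tbl()].
#' @param ... Unused.
#' @return A tibble with columns `time`, `lead`, `mV`.
#' @export
tidy.ecg_tbl <- function(x, ...) {
  chans <- ecg_channels(x)
  tidyr::pivot_longer(as_tibble(x), cols = dplyr::all_of(chans),
                      names_to = "lead", values_to = "mV")
}

#' One-row summary of an ECG tibble
#'
#' @param x An [ecg_tbl()].
#' @param ... Unused.
#' @return A one-row tibble: `n_samples`, `fs`, `duration`, `n_channels`,
#'   and the estimated `bpm` of the first channel (NA when the trace is too
#'   short or the rate is undefined).
#' @export
glance.ecg_tbl <- function(x, ...) {
  fs <- ecg_fs(x)
  dur <- nrow(x) / fs
  bpm <- if (dur >= 5) {
    r <- estimate_beat_rate(x)
    r$bpm
  } else {
    NA_real_
  }
  tibble(
    n_samples = nrow(x), fs = fs, duration = dur,
    n_channels = length(ecg_channels(x)), bpm = bpm
  )
}

#' Tidy a rhythm preset into a parameter table
#'
#' @param x A `rhythm_preset` from [get_preset()].
#' @param ... Unused.
#' @return A tibble with columns `parameter` (dotted path) and `value`
#'   (numeric; angle strings are parsed to radians).
#' @export
tidy.rhythm_preset <- function(x, ...) {
  flat <- unlist(x$raw_params)
  vals <- vapply(flat, function(v) {
    if (is.numeric(v)) v else parse_angle(v)
  }, numeric(1))
  tibble(parameter = names(flat), value = unname(vals))
}

#' One-row summary of a rhythm preset
#'
#' @param x A `rhythm_preset`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `rhythm`, `time_scale`, `gain`,
#'   `n_parameters`, `notes`.
#' @export
glance.rhythm_preset <- function(x, ...) {
  tibble(
    model = x$model, rhythm = x$rhythm, time_scale = x$time_scale,
    gain = x$gain, n_parameters = length(unlist(x$raw_params)),
    notes = x$notes
  )
}
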