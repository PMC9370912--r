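# Einthoven / Goldberger / Wilson lead algebra and 12-lead assembly.

check_electrodes <- function(e) {
  if (!all(c("RA", "LA", "LL") %in% names(e))) {
    abort("electrode potentials need columns RA, LA, LL")
  }
  n <- lengths(e[c("RA", "LA", "LL")])
  if (length(unique(n)) != 1L) abort("RA, LA, LL must have equal lengths")
  invisible(e)
}

#' Bipolar limb leads from electrode potentials
#'
#' Einthoven's bipolar limb leads from the three ground-referenced limb
#' electrode potentials: `I = LA - RA`, `II = LL - RA`, `III = LL - LA`
#' (elementwise). By construction the leads satisfy `II = I + III` and are
#' invariant under a common-mode offset of all three electrodes.
#'
#' @param e Data frame (or named list) with equal-length numeric columns `RA`,
#'   `LA`, `LL` (mV). A `time` column, if present, is carried through.
#' @return A tibble with columns `I`, `II`, `III` (and `time` if supplied).
#' @export
limb_leads <- function(e) {
  check_electrodes(e)
  out <- tibble(
    I = e$LA - e$RA,
    II = e$LL - e$RA,
    III = e$LL - e$LA
  )
  if ("time" %in% names(e)) out <- dplyr::bind_cols(tibble(time = e[["time"]]), out)
  out
}

#' Augmented limb leads from electrode potentials
#'
#' Goldberger's augmented limb leads: each limb electrode referenced to the
#' mean of the other two. The three leads sum to zero identically.
#'
#' @inheritParams limb_leads
#' @return A tibble with columns `aVR`, `aVL`, `aVF` (and `time` if supplied).
#' @export
augmented_leads <- function(e) {
  check_electrodes(e)
  out <- tibble(
    aVR = e$RA - (e$LA + e$LL) / 2,
    aVL = e$LA - (e$RA + e$LL) / 2,
    aVF = e$LL - (e$RA + e$LA) / 2
  )
  if ("time" %in% names(e)) out <- dplyr::bind_cols(tibble(time = e[["time"]]), out)
  out
}

#' Recover electrode potentials from leads I and II
#'
#' Inverts the limb-lead map under the Wilson-terminal gauge
#' `RA + LA + LL = 0` (Wilson central terminal at zero): the unique electrode
#' triple reproducing the given leads is `RA = -(I + II) / 3`, `LA = RA + I`,
#' `LL = RA + II`. Any other gauge differs only by a common-mode offset that
#' the lead differences cancel.
#'
#' @param leadI,leadII Equal-length numeric vectors (mV).
#' @return A tibble with columns `RA`, `LA`, `LL` summing to zero rowwise.
#' @export
solve_electrode_potentials <- function(leadI, leadII) {
  if (length(leadI) != length(leadII)) {
    abort("leads I and II must have equal lengths")
  }
  RA <- -(leadI + leadII) / 3
  tibble(RA = RA, LA = RA + leadI, LL = RA + leadII)
}

lead12_names <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
}

#' Assemble a full 12-lead ECG profile
#'
#' Builds the standard 12-lead set from a heterogeneous-model trajectory.
#' Leads I and II are composed directly from the muscle responses with their
#' per-lead weight rows; III and the augmented leads follow from the exact
#' limb-lead algebra after recovering the electrode potentials under the
#' zero-Wilson-terminal gauge ([solve_electrode_potentials()]); V1-V6 are
#' composed directly from their weight rows (ground-referenced, Wilson
#' terminal at zero). All channels share one time base and one amplitude
#' calibration: the scale is set so the lead-II R peak equals `gain` mV, which
#' preserves inter-lead amplitude ratios, and the Einthoven (`II = I + III`)
#' and Goldberger (`aVR + aVL + aVF = 0`) identities hold by construction.
#'
#' @param trajectory An `ecg_trajectory` from the heterogeneous model.
#' @param params Heterogeneous parameters; default taken from the trajectory.
#' @param fs Output sampling rate (Hz).
#' @param gain Target lead-II R-peak amplitude (mV).
#' @param transient Output-time seconds discarded from the start (default 20%
#'   of the span, capped at 5 s).
#' @param time_scale Time-compression factor (default 1).
#' @return A 12-channel [ecg_tbl()] with channels
#'   I, II, III, aVR, aVL, aVF, V1-V6.
#' @export
twelve_lead_profile <- function(trajectory, params = trajectory$params,
                                fs = 500, gain = 1, transient = NULL,
                                time_scale = 1) {
  stopifnot(inherits(trajectory, "ecg_trajectory"))
  if (trajectory$model != "heterogeneous") {
    abort("a 12-lead profile requires a heterogeneous-model trajectory")
  }
  composed <- c("I", "II", paste0("V", 1:6))
  have <- params$lead_weights$channel
  missing <- setdiff(composed, have)
  if (length(missing)) {
    abort(paste0("missing lead weight row(s): ", paste(missing, collapse = ", ")))
  }

  t_out <- trajectory$time / time_scale
  span <- max(t_out)
  if (is.null(transient)) transient <- default_transient(span)
  if (transient >= span) abort("transient longer than the rendered span")
  grid <- seq(transient, span, by = 1 / fs)

  raw <- lapply(composed, function(ch) {
    v <- compose_ecg_heterogeneous(trajectory$state, params, ch)
    approx(t_out, v, xout = grid)$y
  })
  names(raw) <- composed

  # center I and II, then derive the other limb leads from the centered pair
  # so the Einthoven/Goldberger identities hold exactly
  I <- raw$I - median(raw$I)
  II <- raw$II - median(raw$II)
  el <- solve_electrode_potentials(I, II)
  limb <- limb_leads(el)
  aug <- augmented_leads(el)

  peak <- max(abs(II))
  if (peak == 0) {
    warn("flat lead II; gain calibration falls back to unit scale")
    scale <- 1
  } else {
    scale <- gain / peak
  }
  chans <- c(
    list(I = I, II = II, III = limb$III,
         aVR = aug$aVR, aVL = aug$aVL, aVF = aug$aVF),
    lapply(raw[paste0("V", 1:6)], function(v) v - median(v))
  )
  chans <- lapply(chans, function(v) v * scale)
  ecg_tbl(time = (seq_along(grid) - 1) / fs, channels = chans[lead12_names()],
          fs = fs, model = "heterogeneous")
}
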