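# R-peak detection and beat-rate estimation.

#' Estimate the beat rate of an ECG trace
#'
#' Detects R peaks on the absolute baseline-corrected signal (so leads with a
#' negative-dominant QRS are handled symmetrically) by an adaptive amplitude
#' threshold: a fraction (default 0.6) of the 98th-percentile magnitude of
#' the candidate local maxima, with a refractory window (default 0.2 s) that
#' keeps only the largest excursion within each window. The rate is
#' `60 / median(RR)` over the detected inter-peak intervals. The rhythm is
#' flagged irregular when the relative spread `IQR(RR) / median(RR)` exceeds
#' 0.1 (the behavior expected of fibrillation presets); with fewer than two
#' detected peaks the rate is undefined and flagged.
#'
#' @param x An [ecg_tbl()] (first channel is used unless `channel` is given)
#'   or a numeric vector with `fs` supplied.
#' @param fs Sampling rate in Hz (taken from `x` when it is an `ecg_tbl`).
#' @param channel Channel name to analyze when `x` has several.
#' @param threshold Fraction of the 98th-percentile amplitude used as the
#'   detection threshold.
#' @param refractory Refractory window in seconds.
#' @return A one-row tibble with columns `bpm`, `n_peaks`, `rr_median`,
#'   `rr_spread` (IQR/median), `irregular`, `undefined`.
#' @export
estimate_beat_rate <- function(x, fs = NULL, channel = NULL,
                               threshold = 0.6, refractory = 0.2) {
  if (is.data.frame(x)) {
    if (is.null(fs)) fs <- ecg_fs(x)
    chans <- ecg_channels(x)
    if (is.null(channel)) channel <- chans[1]
    if (!channel %in% chans) {
      abort(paste0("no channel '", channel, "'; available: ",
                   paste(chans, collapse = ", ")))
    }
    v <- x[[channel]]
  } else {
    if (is.null(fs)) abort("`fs` is required for a bare numeric trace")
    v <- as.numeric(x)
  }
  if (length(v) / fs < 5) abort("at least 5 s of signal are required")

  undefined_result <- function(n) tibble(
    bpm = NA_real_, n_peaks = n, rr_median = NA_real_,
    rr_spread = NA_real_, irregular = NA, undefined = TRUE
  )

  v0 <- abs(v - median(v))
  n <- length(v0)
  is_max <- c(FALSE, v0[2:(n - 1)] >= v0[1:(n - 2)] &
                v0[2:(n - 1)] > v0[3:n], FALSE)
  maxima <- which(is_max & v0 > 0)
  if (length(maxima) == 0) return(undefined_result(0L))
  amp <- as.numeric(quantile(v0[maxima], 0.98))
  thr <- threshold * amp
  cand <- maxima[v0[maxima] > thr]
  if (length(cand) == 0) return(undefined_result(0L))

  refr <- refractory * fs
  kept <- cand[1]
  for (i in cand[-1]) {
    last <- kept[length(kept)]
    if (i - last > refr) {
      kept <- c(kept, i)
    } else if (v0[i] > v0[last]) {
      kept[length(kept)] <- i
    }
  }
  if (length(kept) < 2) return(undefined_result(length(kept)))

  rr <- diff(kept) / fs
  rr_med <- median(rr)
  rr_spread <- as.numeric(diff(quantile(rr, c(0.25, 0.75)))) / rr_med
  tibble(
    bpm = 60 / rr_med,
    n_peaks = length(kept),
    rr_median = rr_med,
    rr_spread = rr_spread,
    irregular = rr_spread > 0.1,
    undefined = FALSE
  )
}
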