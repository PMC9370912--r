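# Stochastic RR-interval (tachogram) generation for the quasi-periodic model.

#' Specify a stochastic RR-interval series
#'
#' Describes beat-to-beat heart-period variability as a stationary Gaussian
#' process with the classic bimodal heart-rate-variability spectrum: a
#' low-frequency (Mayer-wave) Gaussian band and a high-frequency (respiratory)
#' band. Realizations are drawn by [rr_tachogram()] and drive the per-beat
#' angular frequency of the quasi-periodic model.
#'
#' @param hr_mean Mean heart rate, beats per minute.
#' @param hr_std Standard deviation of the heart rate, beats per minute.
#' @param f_lf,f_hf Center frequencies of the LF and HF bands (Hz).
#' @param c_lf,c_hf Band widths (Hz).
#' @param lf_hf_ratio Ratio of LF to HF band power.
#' @return An `rr_tachogram_spec` list.
#' @export
rr_tachogram_spec <- function(hr_mean = 60, hr_std = 5,
                              f_lf = 0.1, f_hf = 0.25,
                              c_lf = 0.01, c_hf = 0.01,
                              lf_hf_ratio = 0.5) {
  check_finite(c(hr_mean, hr_std, f_lf, f_hf, c_lf, c_hf, lf_hf_ratio),
               "tachogram parameters")
  if (hr_mean <= 0) abort("`hr_mean` must be > 0")
  if (hr_std < 0) abort("`hr_std` must be >= 0")
  structure(
    list(hr_mean = hr_mean, hr_std = hr_std, f_lf = f_lf, f_hf = f_hf,
         c_lf = c_lf, c_hf = c_hf, lf_hf_ratio = lf_hf_ratio),
    class = "rr_tachogram_spec"
  )
}

with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Draw a beat-to-beat RR-interval series
#'
#' Synthesizes `n_beats` RR intervals (seconds) from the bimodal spectrum of
#' an [rr_tachogram_spec()]: spectral amplitudes are fixed by the band model,
#' phases are drawn uniformly at random (seeded), and the inverse FFT yields a
#' Gaussian series that is rescaled to the requested heart-rate mean and
#' standard deviation (converted to RR units). Intervals are clamped to the
#' physiological range \[0.2, 3\] s.
#'
#' @param spec An [rr_tachogram_spec()].
#' @param n_beats Number of intervals to draw.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return Numeric vector of RR intervals in seconds.
#' @export
rr_tachogram <- function(spec, n_beats, seed = NULL) {
  stopifnot(inherits(spec, "rr_tachogram_spec"), n_beats >= 1)
  rr_mean <- 60 / spec$hr_mean
  rr_std <- 60 * spec$hr_std / spec$hr_mean^2
  if (rr_std == 0) return(rep(rr_mean, n_beats))
  N <- 2^ceiling(log2(max(n_beats, 64)))
  # tachogram treated as sampled at 1 Hz in "beat time"; one-sided bands
  f <- seq(0, 0.5, length.out = N / 2 + 1)
  S <- spec$lf_hf_ratio * exp(-(f - spec$f_lf)^2 / (2 * spec$c_lf^2)) +
    exp(-(f - spec$f_hf)^2 / (2 * spec$c_hf^2))
  amp <- sqrt(S)
  x <- with_preserved_seed(seed, {
    phase <- stats::runif(N / 2 + 1, 0, 2 * pi)
    spec_full <- complex(modulus = c(amp, rev(amp[2:(N / 2)])),
                         argument = c(phase, -rev(phase[2:(N / 2)])))
    Re(stats::fft(spec_full, inverse = TRUE)) / N
  })
  x <- x[seq_len(n_beats)]
  x <- (x - mean(x)) / max(stats::sd(x), .Machine$double.eps)
  pmin(pmax(rr_mean + rr_std * x, 0.2), 3)
}
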