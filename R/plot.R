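# ggplot2 display of ECG tibbles.

#' @importFrom ggplot2 autoplot ggplot aes geom_line facet_wrap labs vars
#'   theme_minimal
NULL

#' Plot an ECG tibble
#'
#' Line plot of each channel against time, faceted in reading order for
#' multi-lead sets (fixed y scale across leads, as on clinical ECG paper).
#'
#' @param object An [ecg_tbl()].
#' @param channels Optional subset of channel names to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_tbl <- function(object, channels = NULL, ...) {
  chans <- ecg_channels(object)
  if (!is.null(channels)) chans <- intersect(channels, chans)
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("time", chans)],
    cols = dplyr::all_of(chans), names_to = "lead", values_to = "mV"
  )
  long$lead <- factor(long$lead, levels = chans)
  ncol <- if (length(chans) > 6) 3L else 1L
  ggplot(long, aes(x = .data$time, y = .data$mV)) +
    geom_line(linewidth = 0.3, colour = "#b2182b") +
    facet_wrap(vars(.data$lead), ncol = ncol) +
    labs(x = "time (s)", y = "amplitude (mV)") +
    theme_minimal()
}

#' @rdname autoplot.ecg_tbl
#' @param x An [ecg_tbl()].
#' @export
plot_ecg <- function(x, channels = NULL, ...) autoplot.ecg_tbl(x, channels, ...)
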