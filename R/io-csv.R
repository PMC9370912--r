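# CSV serialization: header time_s,<channel>...; full-precision decimals
# (%.17g round-trips IEEE doubles exactly); UTF-8; LF line endings.

#' Write ECG traces to CSV
#'
#' One time column (`time_s`, seconds) followed by one column per channel
#' (mV). Values are printed with 17 significant digits so a write-read-write
#' cycle is byte-identical.
#'
#' @param x An [ecg_tbl()] or data frame with a `time` column and at least one
#'   channel column, all of equal length.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(x, path) {
  chans <- setdiff(names(x), "time")
  if (length(chans) == 0) abort("at least one channel column is required")
  if (!"time" %in% names(x)) abort("a `time` column is required")
  cols <- c(list(x$time), lapply(chans, function(ch) x[[ch]]))
  body <- do.call(paste, c(lapply(cols, function(v) sprintf("%.17g", v)),
                           sep = ","))
  con <- file(path, open = "wb") # binary: LF endings on every platform
  on.exit(close(con))
  writeLines(c(paste(c("time_s", chans), collapse = ","), body), con,
             sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read ECG traces from CSV
#'
#' @param path A file written by [write_ecg_csv()].
#' @return An [ecg_tbl()]; the sampling rate is recovered from the median time
#'   step.
#' @export
read_ecg_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) abort("not an ECG CSV: missing time_s column")
  time <- df$time_s
  chans <- df[setdiff(names(df), "time_s")]
  fs <- 1 / median(diff(time))
  ecg_tbl(time = time, channels = as.list(chans), fs = fs)
}
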