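# Minimal WFDB record writer/reader: standard .hea header plus a format-16
# signal file (16-bit two's-complement little-endian, frame-interleaved).
# Written from scratch against the published header/format conventions; no
# WFDB library is required to read the records back.

int16_checksum <- function(digital) {
  s <- sum(as.numeric(digital)) %% 65536
  if (s > 32767) s <- s - 65536
  as.integer(s)
}

#' Write ECG traces as a WFDB record
#'
#' Emits `record.hea` and `record.dat` (format 16). The per-channel ADC gain
#' is chosen as `floor(32000 / max|x|)` units per mV so the signal's dynamic
#' range maps into the 16-bit integer range without clipping; an amplitude
#' too large to represent at gain >= 1 raises an error rather than clipping
#' silently. Reading the record back reproduces each sample within one
#' quantization step (`1 / gain` mV).
#'
#' @param x An [ecg_tbl()] (or data frame with `time` + channel columns).
#' @param record Record name; must not contain path separators.
#' @param dir Output directory.
#' @return The record name, invisibly.
#' @export
write_wfdb <- function(x, record, dir = ".") {
  if (grepl("[/\\\\]", record)) {
    abort("`record` must be a bare name without path separators")
  }
  chans <- setdiff(names(x), "time")
  if (length(chans) == 0) abort("at least one channel column is required")
  fs <- ecg_fs(x)
  nsamp <- nrow(x)
  sig <- vapply(chans, function(ch) as.numeric(x[[ch]]),
                numeric(nsamp))
  sig <- matrix(sig, nrow = nsamp)

  gains <- integer(length(chans))
  digital <- matrix(0L, nsamp, length(chans))
  for (j in seq_along(chans)) {
    maxabs <- max(abs(sig[, j]))
    g <- if (maxabs == 0) 200L else as.integer(floor(32000 / maxabs))
    if (g < 1L) {
      abort(paste0("channel ", chans[j],
                   ": amplitude exceeds the representable range"))
    }
    gains[j] <- g
    digital[, j] <- as.integer(round(sig[, j] * g))
  }

  hea <- c(
    paste(record, length(chans), format(fs), nsamp),
    vapply(seq_along(chans), function(j) {
      sprintf("%s.dat 16 %d(0)/mV 16 0 %d %d 0 %s",
              record, gains[j], digital[1, j],
              int16_checksum(digital[, j]), chans[j])
    }, character(1))
  )
  writeLines(hea, file.path(dir, paste0(record, ".hea")))

  con <- file(file.path(dir, paste0(record, ".dat")), open = "wb")
  on.exit(close(con))
  writeBin(as.integer(t(digital)), con, size = 2L, endian = "little")
  invisible(record)
}

#' Read a WFDB record written by [write_wfdb()]
#'
#' Parses the header and the format-16 signal file and rescales each channel
#' by its ADC gain.
#'
#' @param record Record name.
#' @param dir Directory holding `record.hea` and `record.dat`.
#' @return An [ecg_tbl()] with the record's channels in mV.
#' @export
read_wfdb <- function(record, dir = ".") {
  hea <- readLines(file.path(dir, paste0(record, ".hea")))
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])

  gains <- numeric(nsig)
  labels <- character(nsig)
  for (j in seq_len(nsig)) {
    f <- strsplit(trimws(hea[1 + j]), "\\s+")[[1]]
    gains[j] <- as.numeric(sub("\\(.*$", "", f[3]))
    labels[j] <- paste(f[9:length(f)], collapse = " ")
  }

  con <- file(file.path(dir, paste0(record, ".dat")), open = "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "integer", n = nsig * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  digital <- matrix(raw, ncol = nsig, byrow = TRUE)
  chans <- lapply(seq_len(nsig), function(j) digital[, j] / gains[j])
  names(chans) <- labels
  ecg_tbl(time = (seq_len(nsamp) - 1L) / fs, channels = chans, fs = fs)
}
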