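# Minimal EDF (European Data Format) reader/writer for continuous
# multichannel recordings: 256-byte fixed header, 256 bytes per signal,
# 16-bit little-endian samples with per-channel physical/digital scaling.
# Covers the subset of EDF this package needs (equal sampling rate across
# channels, numeric data, single continuous recording).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  data <- rec$data
  nch <- nrow(data)
  nsamp <- ncol(data)
  phys_min <- apply(data, 1L, min)
  phys_max <- apply(data, 1L, max)
  flat <- phys_max - phys_min <= 0
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  duration <- nsamp / rec$fs

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(paste("Startdate 01-JAN-2000", "X", "X", "fractalEEG"), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + nch), 8),
    edf_pad("", 44),
    edf_pad(1L, 8),
    edf_pad(format(duration, digits = 8), 8),
    edf_pad(nch, 4)
  )
  sig <- paste0(
    paste(vapply(rec$labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), nch), collapse = ""),
    paste(rep(edf_pad("uV", 8), nch), collapse = ""),
    paste(vapply(phys_min, function(v) edf_pad(format(v, digits = 7), 8), ""),
          collapse = ""),
    paste(vapply(phys_max, function(v) edf_pad(format(v, digits = 7), 8), ""),
          collapse = ""),
    paste(rep(edf_pad(dig_min, 8), nch), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), nch), collapse = ""),
    paste(rep(edf_pad("", 80), nch), collapse = ""),
    paste(rep(edf_pad(nsamp, 8), nch), collapse = ""),
    paste(rep(edf_pad("", 32), nch), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  for (i in seq_len(nch)) {
    scl <- (dig_max - dig_min) / (phys_max[i] - phys_min[i])
    dig <- round((data[i, ] - phys_min[i]) * scl) + dig_min
    writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path, group = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_records <- as.integer(rd(8))
  duration <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (!is.finite(nch) || nch < 1L) stop_invalid("EDF parse error: bad channel count")
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)          # transducer
  for (i in seq_len(nch)) rd(8)           # dimension
  phys_min <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nch)) rd(80)          # prefilter
  nspr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nch)) rd(32)
  fs <- nspr / duration
  if (length(unique(fs)) != 1L) {
    stop_invalid("EDF files with per-channel sampling rates are not supported")
  }
  data <- matrix(0, nch, nspr[1] * n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(nch)) {
      dig <- readBin(con, "integer", n = nspr[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- (dig - dig_min[i]) * (phys_max[i] - phys_min[i]) /
        (dig_max[i] - dig_min[i]) + phys_min[i]
      data[i, ((r - 1L) * nspr[i] + 1L):(r * nspr[i])] <- phys
    }
  }
  if (any(!is.finite(data))) stop_invalid("EDF contains non-finite samples")
  recording(data, fs[1], labels, group = group)
}
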