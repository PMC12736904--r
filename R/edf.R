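# Minimal EDF (European Data Format) support: fixed-layout ASCII header
# (256 bytes + 256 per signal) followed by int16 little-endian samples.
# One data record per file on write; arbitrary record counts on read.
# Physical values are recovered via the per-signal linear calibration.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a recording as EDF
#'
#' Writes a single-data-record EDF file with 16-bit quantisation over each
#' channel's observed amplitude range. Intended for fixture generation and
#' interchange; quantisation means amplitudes round-trip to ~1/65536 of
#' the channel range, not bit-exactly.
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  data <- recording$data
  ns <- ncol(data)
  n <- nrow(data)
  phys_min <- apply(data, 2, min)
  phys_max <- apply(data, 2, max)
  flat <- phys_max == phys_min
  phys_max[flat] <- phys_min[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(recording$subject_id, 80),
    edf_field("arcnet export", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 * (ns + 1), 8),
    edf_field("", 44),
    edf_field(1, 8),
    edf_field(format(n / recording$fs, digits = 7), 8),
    edf_field(ns, 4),
    paste(vapply(recording$channels, edf_field, "", width = 16),
          collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field("uV", 8), ns), collapse = ""),
    paste(vapply(phys_min, function(v) edf_field(format(v, digits = 7), 8),
                 ""), collapse = ""),
    paste(vapply(phys_max, function(v) edf_field(format(v, digits = 7), 8),
                 ""), collapse = ""),
    paste(rep(edf_field(-32768, 8), ns), collapse = ""),
    paste(rep(edf_field(32767, 8), ns), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field(n, 8), ns), collapse = ""),
    paste(rep(edf_field("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  for (ch in seq_len(ns)) {
    dig <- round((data[, ch] - phys_min[ch]) /
                   (phys_max[ch] - phys_min[ch]) * 65535 - 32768)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rc <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rc(8)
  if (version != "0")
    stop("not an EDF file (bad version field): ", path)
  patient <- rc(80)
  rc(80); rc(8); rc(8)
  rc(8)                                    # header byte count
  reserved <- rc(44)
  if (grepl("^EDF\\+D", reserved))
    stop("discontinuous EDF+ files are not supported")
  ndr <- as.integer(rc(8))
  dur <- as.numeric(rc(8))
  ns <- as.integer(rc(4))
  if (is.na(ns) || ns < 1) stop("EDF file declares zero signals: ", path)
  labels <- vapply(seq_len(ns), function(i) rc(16), "")
  vapply(seq_len(ns), function(i) rc(80), "")
  dims <- vapply(seq_len(ns), function(i) rc(8), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rc(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rc(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rc(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rc(8), ""))
  vapply(seq_len(ns), function(i) rc(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rc(8), ""))
  vapply(seq_len(ns), function(i) rc(32), "")
  if (anyNA(c(ndr, dur, spr)))
    stop("malformed EDF header (record counts): ", path)
  chans <- lapply(seq_len(ns), function(i) numeric(0))
  for (r in seq_len(ndr)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2,
                     endian = "little")
      if (length(dig) < spr[ch])
        stop("EDF data truncated in record ", r, " signal ", ch)
      chans[[ch]] <- c(chans[[ch]],
                       (dig - dig_min[ch]) *
                         (phys_max[ch] - phys_min[ch]) /
                         (dig_max[ch] - dig_min[ch]) + phys_min[ch])
    }
  }
  fs <- spr[1] / dur
  data <- do.call(cbind, chans)
  colnames(data) <- make.unique(labels)
  units <- if (all(grepl("uV", dims))) "uV" else "unknown"
  sid <- bids_subject_id(path)
  if (is.na(sid)) sid <- if (nzchar(patient)) patient else
    sub("\\.[^.]*$", "", basename(path))
  eeg_recording(data, fs = fs, subject_id = sid, units = units)
}
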