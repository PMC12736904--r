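#' EEG recording and segment containers
#'
#' `eeg_recording()` holds a multi-channel recording: an amplitude matrix
#' (samples x channels, microvolts when the source format declares units),
#' the sampling rate and subject metadata. `eeg_segment()` holds one
#' fixed-length single-channel analysis window — the unit the ARC
#' transformation operates on.
#'
#' @param data Numeric matrix, samples in rows, one column per channel,
#'   with channel labels (10-20 system names such as Fp1...O2) as column
#'   names.
#' @param fs Sampling rate in Hz (> 0).
#' @param subject_id Opaque subject identifier string.
#' @param group_label Optional class label (`"AD"`, `"FTD"`, `"HC"`) or
#'   `NA`.
#' @param units Amplitude units; `"uV"` or `"unknown"`. Unknown units are
#'   passed through unscaled — ARC topology is invariant to amplitude
#'   shifts but not to rescaling, so a warning is emitted.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, subject_id = "unknown",
                          group_label = NA_character_, units = "uV") {
  data <- as.matrix(data)
  if (ncol(data) == 0) stop("empty recording: zero channels")
  if (nrow(data) < 2) stop("channels must have length >= 2")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(colnames(data)))
    colnames(data) <- sprintf("ch%02d", seq_len(ncol(data)))
  if (!identical(units, "uV"))
    warning("amplitude units are '", units,
            "'; values passed through unscaled")
  structure(list(data = data, channels = colnames(data), fs = fs,
                 subject_id = subject_id, group_label = group_label,
                 units = units),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording '%s': %d channels x %d samples @ %g Hz\n",
              x$subject_id, ncol(x$data), nrow(x$data), x$fs))
  cat("  channels:", paste(utils::head(x$channels, 8), collapse = ", "),
      if (length(x$channels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @rdname eeg_recording
#' @param x Numeric amplitude series (length >= 2, all finite).
#' @param channel Channel label of origin.
#' @param window_index 0-based index of the window within its channel.
#' @export
eeg_segment <- function(x, fs, subject_id = "unknown", channel = "ch01",
                        window_index = 0L) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("segment must contain at least 2 samples")
  if (!all(is.finite(x))) stop("segment contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  structure(list(x = x, fs = fs,
                 source = list(subject_id = subject_id, channel = channel,
                               window_index = as.integer(window_index))),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("EEG segment: %d samples @ %g Hz (%.3g s) [%s / %s / win %d]\n",
              length(x$x), x$fs, length(x$x) / x$fs,
              x$source$subject_id, x$source$channel,
              x$source$window_index))
  invisible(x)
}

#' Cut a fixed-length analysis window from a recording
#'
#' Windows are half-open 0-based sample ranges `[start, start +
#' window_samples)`. The default window is 20000 samples — 40 s at the
#' 500 Hz rate typical of clinical EEG. Consecutive non-overlapping starts
#' partition the channel exactly.
#'
#' @param recording An [eeg_recording()].
#' @param channel Channel label (must be present in the recording).
#' @param window_samples Window length in samples (default 20000).
#' @param start 0-based sample offset of the window (default 0).
#' @return An [eeg_segment()].
#' @examples
#' rec <- eeg_recording(matrix(rnorm(100), ncol = 1,
#'                             dimnames = list(NULL, "Fp1")), fs = 500)
#' seg <- get_segment(rec, "Fp1", window_samples = 50, start = 25)
#' @export
get_segment <- function(recording, channel, window_samples = 20000L,
                        start = 0L) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!channel %in% recording$channels)
    stop("channel '", channel, "' not found; available: ",
         paste(recording$channels, collapse = ", "))
  window_samples <- as.integer(window_samples)
  start <- as.integer(start)
  if (window_samples < 2) stop("window_samples must be >= 2")
  if (start < 0) stop("start must be >= 0")
  len <- nrow(recording$data)
  if (start + window_samples > len)
    stop("window [", start, ", ", start + window_samples,
         ") exceeds channel length ", len)
  eeg_segment(recording$data[(start + 1L):(start + window_samples), channel],
              fs = recording$fs, subject_id = recording$subject_id,
              channel = channel,
              window_index = start %/% window_samples)
}
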