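#' Extract the BIDS subject identifier from a path
#'
#' Matches the `sub-<label>` entity anywhere in the path (e.g.
#' `sub-001/eeg/sub-001_task-eyesclosed_eeg.set` gives `"sub-001"`).
#'
#' @param path File path.
#' @return The subject id string, or `NA` when the path carries none.
#' @export
bids_subject_id <- function(path) {
  m <- regmatches(path, regexpr("sub-[A-Za-z0-9]+", path))
  if (length(m)) m[[1]] else NA_character_
}

#' Load an EEG recording from disk
#'
#' Supported formats: delimited text (CSV/TSV, one column per channel,
#' optional header row of channel labels), EDF, and EEGLAB SET files in a
#' BIDS layout (`sub-*/eeg/*_eeg.set`; continuous data only). Amplitudes
#' are returned in microvolts when the format declares units (EDF physical
#' dimension, EEGLAB convention); delimited text carries no units and is
#' passed through unscaled with a warning. The subject id is taken from
#' the BIDS `sub-` entity when present, otherwise from the file name.
#'
#' @param path File path.
#' @param format `"auto"` (by extension) or one of `"csv"`, `"edf"`,
#'   `"eeglab_set"`.
#' @param fs Sampling rate in Hz for delimited text (which does not store
#'   one); ignored for EDF/SET.
#' @param fs_expected If not `NULL`, warn when the file's sampling rate
#'   differs (default 500).
#' @param group_label Optional class label to attach.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf",
                                            "eeglab_set"),
                           fs = 500, fs_expected = NULL,
                           group_label = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, csv = "csv", tsv = "csv", txt = "csv",
                     edf = "edf", set = "eeglab_set",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format= explicitly"))
  }
  rec <- switch(format,
                csv = read_recording_csv(path, fs = fs),
                edf = read_edf(path),
                eeglab_set = read_eeglab_set(path))
  rec$group_label <- group_label
  if (!is.null(fs_expected) && rec$fs != fs_expected)
    warning("sampling rate ", rec$fs, " Hz differs from expected ",
            fs_expected, " Hz")
  rec
}

read_recording_csv <- function(path, fs) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  d <- utils::read.table(path, header = has_header, sep = sep)
  if (ncol(d) == 0 || nrow(d) == 0) stop("empty recording: ", path)
  if (!all(vapply(d, is.numeric, logical(1))))
    stop("non-numeric column in delimited recording: ", path)
  data <- as.matrix(d)
  if (!has_header) colnames(data) <- sprintf("ch%02d", seq_len(ncol(data)))
  sid <- bids_subject_id(path)
  if (is.na(sid)) sid <- sub("\\.[^.]*$", "", basename(path))
  eeg_recording(data, fs = fs, subject_id = sid, units = "unknown")
}

#' Write a recording as CSV
#'
#' One column per channel, header row of channel labels, amplitudes
#' printed with 17 significant digits so that a CSV round-trip reproduces
#' them bit-exactly.
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  txt <- apply(recording$data, 2, function(col) sprintf("%.17g", col))
  lines <- c(paste(recording$channels, collapse = ","),
             apply(txt, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
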