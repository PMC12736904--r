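# Minimal MAT-file v5 writer for EEGLAB SET fixtures (uncompressed,
# little-endian, full-size tags). Only what the fixtures need: double
# matrices, char arrays and structs.

mat_pad8 <- function(bytes) {
  rem <- length(bytes) %% 8
  if (rem) c(bytes, raw(8 - rem)) else bytes
}

mat_tag <- function(type, nbytes) {
  c(writeBin(as.integer(type), raw(), size = 4, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4, endian = "little"))
}

mat_el <- function(type, payload) {
  c(mat_tag(type, length(payload)), mat_pad8(payload))
}

mat_numeric <- function(v, dims, name) {
  flags <- c(writeBin(6L, raw(), size = 4, endian = "little"),  # mxDOUBLE
             raw(4))
  body <- c(mat_el(6, flags),
            mat_el(5, writeBin(as.integer(dims), raw(), size = 4,
                               endian = "little")),
            mat_el(1, charToRaw(name)),
            mat_el(9, writeBin(as.numeric(v), raw(), size = 8,
                               endian = "little")))
  mat_el(14, body)
}

mat_char <- function(s, name) {
  codes <- utf8ToInt(s)
  flags <- c(writeBin(4L, raw(), size = 4, endian = "little"), raw(4))
  body <- c(mat_el(6, flags),
            mat_el(5, writeBin(c(1L, length(codes)), raw(), size = 4,
                               endian = "little")),
            mat_el(1, charToRaw(name)),
            mat_el(4, writeBin(as.integer(codes), raw(), size = 2,
                               endian = "little")))
  mat_el(14, body)
}

# elements: list (one per struct array element) of named lists of raw
# miMATRIX blobs built with empty names.
mat_struct <- function(elements, dims, name) {
  fields <- names(elements[[1]])
  flags <- c(writeBin(2L, raw(), size = 4, endian = "little"), raw(4))
  fnames <- unlist(lapply(fields, function(f) {
    b <- charToRaw(f)
    c(b, raw(32 - length(b)))
  }))
  body <- c(mat_el(6, flags),
            mat_el(5, writeBin(as.integer(dims), raw(), size = 4,
                               endian = "little")),
            mat_el(1, charToRaw(name)),
            mat_el(5, writeBin(32L, raw(), size = 4, endian = "little")),
            mat_el(1, fnames),
            unlist(lapply(elements, function(el) unlist(el))))
  mat_el(14, body)
}

write_set_fixture <- function(path, data, srate, labels,
                              trials = 1, epoched = FALSE) {
  nbchan <- nrow(data)
  pnts <- ncol(data)
  chanlocs <- lapply(labels, function(l) list(labels = mat_char(l, "")))
  eeg <- mat_struct(list(list(
    data = mat_numeric(data, dim(data), ""),
    srate = mat_numeric(srate, c(1, 1), ""),
    nbchan = mat_numeric(nbchan, c(1, 1), ""),
    pnts = mat_numeric(pnts, c(1, 1), ""),
    trials = mat_numeric(if (epoched) 2 else trials, c(1, 1), ""),
    chanlocs = mat_struct(chanlocs, c(1, nbchan), ""))),
    c(1, 1), "EEG")
  txt <- charToRaw(sprintf("MATLAB 5.0 MAT-file, test fixture"))
  header <- c(txt, rep(charToRaw(" "), 116 - length(txt)),
              raw(8),
              writeBin(256L, raw(), size = 2, endian = "little"),
              charToRaw("IM"))
  writeBin(c(header, eeg), path)
  invisible(path)
}
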