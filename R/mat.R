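# Minimal MAT-file v5 reader, covering the subset EEGLAB SET files use:
# uncompressed little-endian files with numeric arrays, char arrays,
# struct (arrays) and cells. Compressed (v7) and HDF5-based (v7.3) files
# are rejected with an explicit error.

mat5_u32 <- function(raw, at) {
  v <- readBin(raw[at:(at + 3)], "integer", size = 4, endian = "little")
  if (v < 0) v + 2^32 else as.numeric(v)
}

mat5_decode_numeric <- function(mi_type, bytes) {
  switch(as.character(mi_type),
    "1" = as.numeric(readBin(bytes, "integer", n = length(bytes), size = 1,
                             signed = TRUE)),
    "2" = as.numeric(readBin(bytes, "integer", n = length(bytes), size = 1,
                             signed = FALSE)),
    "3" = as.numeric(readBin(bytes, "integer", n = length(bytes) / 2,
                             size = 2, signed = TRUE, endian = "little")),
    "4" = as.numeric(readBin(bytes, "integer", n = length(bytes) / 2,
                             size = 2, signed = FALSE, endian = "little")),
    "5" = as.numeric(readBin(bytes, "integer", n = length(bytes) / 4,
                             size = 4, endian = "little")),
    "6" = vapply(seq_len(length(bytes) / 4),
                 function(i) mat5_u32(bytes, 4 * i - 3), numeric(1)),
    "7" = as.numeric(readBin(bytes, "double", n = length(bytes) / 4,
                             size = 4, endian = "little")),
    "9" = readBin(bytes, "double", n = length(bytes) / 8, size = 8,
                  endian = "little"),
    stop("unsupported MAT data type ", mi_type))
}

# Returns list(type, bytes, next_pos); handles the small-element format.
mat5_element <- function(raw, pos) {
  type <- mat5_u32(raw, pos)
  small_len <- type %/% 65536
  if (small_len > 0) {
    type <- type %% 65536
    bytes <- if (small_len > 0) raw[(pos + 4):(pos + 3 + small_len)] else raw(0)
    return(list(type = type, bytes = bytes, next_pos = pos + 8))
  }
  nbytes <- mat5_u32(raw, pos + 4)
  bytes <- if (nbytes > 0) raw[(pos + 8):(pos + 7 + nbytes)] else raw(0)
  pad <- ceiling(nbytes / 8) * 8
  list(type = type, bytes = bytes, next_pos = pos + 8 + pad)
}

mat5_chars <- function(mi_type, bytes) {
  if (mi_type %in% c(3, 4, 17)) {
    codes <- readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                     signed = FALSE, endian = "little")
    intToUtf8(codes[codes > 0])
  } else {
    rawToChar(bytes[bytes != as.raw(0)])
  }
}

mat5_matrix <- function(bytes) {
  pos <- 1
  flags <- mat5_element(bytes, pos)
  cls <- as.integer(flags$bytes[1])
  pos <- flags$next_pos
  dims_el <- mat5_element(bytes, pos)
  dims <- mat5_decode_numeric(dims_el$type, dims_el$bytes)
  pos <- dims_el$next_pos
  name_el <- mat5_element(bytes, pos)
  name <- rawToChar(name_el$bytes[name_el$bytes != as.raw(0)])
  pos <- name_el$next_pos

  value <- if (cls == 4) {                       # mxCHAR
    el <- mat5_element(bytes, pos)
    mat5_chars(el$type, el$bytes)
  } else if (cls %in% c(6, 7, 8, 9, 10, 11, 12, 13)) {  # numeric
    el <- mat5_element(bytes, pos)
    v <- mat5_decode_numeric(el$type, el$bytes)
    if (length(dims) == 2 && all(dims > 0)) dim(v) <- dims
    v
  } else if (cls == 2) {                         # mxSTRUCT
    fnl_el <- mat5_element(bytes, pos)
    fnl <- mat5_decode_numeric(fnl_el$type, fnl_el$bytes)[1]
    pos <- fnl_el$next_pos
    names_el <- mat5_element(bytes, pos)
    n_fields <- length(names_el$bytes) / fnl
    fields <- vapply(seq_len(n_fields), function(i) {
      b <- names_el$bytes[((i - 1) * fnl + 1):(i * fnl)]
      rawToChar(b[b != as.raw(0)])
    }, "")
    pos <- names_el$next_pos
    n_el <- prod(dims)
    elements <- vector("list", n_el)
    for (e in seq_len(n_el)) {
      item <- stats::setNames(vector("list", n_fields), fields)
      for (f in seq_len(n_fields)) {
        sub <- mat5_element(bytes, pos)
        if (sub$type != 14) stop("malformed struct field (not miMATRIX)")
        parsed <- mat5_matrix(sub$bytes)
        item[[f]] <- parsed$value
        pos <- sub$next_pos
      }
      elements[[e]] <- item
    }
    if (n_el == 1) elements[[1]] else elements
  } else if (cls == 1) {                         # mxCELL
    n_el <- prod(dims)
    items <- vector("list", n_el)
    for (e in seq_len(n_el)) {
      sub <- mat5_element(bytes, pos)
      parsed <- mat5_matrix(sub$bytes)
      items[[e]] <- parsed$value
      pos <- sub$next_pos
    }
    items
  } else {
    stop("unsupported MAT array class ", cls)
  }
  list(name = name, value = value)
}

read_mat5 <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 128) stop("not a MAT-file (too short): ", path)
  if (raw[1] == as.raw(0x89) && rawToChar(raw[2:4]) == "HDF")
    stop("MAT v7.3 (HDF5) files are not supported; save as v6")
  text <- rawToChar(raw[1:116])
  if (!grepl("^MATLAB 5\\.0", text))
    stop("not a MAT-file v5 header: ", path)
  endian <- rawToChar(raw[127:128])
  if (endian != "IM") stop("big-endian MAT-files are not supported")
  pos <- 129
  out <- list()
  while (pos + 7 <= length(raw)) {
    el <- mat5_element(raw, pos)
    if (el$type == 15)
      stop("compressed MAT-file (v7); save with '-v6' to use this reader")
    if (el$type != 14) stop("unexpected top-level MAT element type ",
                            el$type)
    parsed <- mat5_matrix(el$bytes)
    out[[parsed$name]] <- parsed$value
    pos <- el$next_pos
  }
  out
}

# EEGLAB SET: a MAT-file holding the struct EEG (or its fields as
# top-level variables). Continuous data only; epoched files are rejected.
read_eeglab_set <- function(path) {
  vars <- read_mat5(path)
  eeg <- if (!is.null(vars$EEG)) vars$EEG else vars
  if (is.null(eeg$data) || is.null(eeg$srate))
    stop("not an EEGLAB SET file (missing data/srate): ", path)
  trials <- if (!is.null(eeg$trials)) eeg$trials[1] else 1
  if (trials > 1 || (is.numeric(eeg$data) && length(dim(eeg$data)) > 2))
    stop("epoched SET files are not supported; expected continuous data")
  if (is.character(eeg$data)) {                 # payload in a .fdt file
    fdt <- file.path(dirname(path), basename(eeg$data))
    if (!file.exists(fdt))
      fdt <- sub("\\.set$", ".fdt", path)
    if (!file.exists(fdt))
      stop("SET file points to missing float payload: ", eeg$data)
    nbchan <- eeg$nbchan[1]
    vals <- readBin(fdt, "double", n = file.size(fdt) / 4, size = 4,
                    endian = "little")
    data <- t(matrix(vals, nrow = nbchan))
  } else {
    data <- t(eeg$data)                         # nbchan x pnts on disk
  }
  labels <- NULL
  if (!is.null(eeg$chanlocs)) {
    locs <- eeg$chanlocs
    if (!is.null(names(locs))) locs <- list(locs)
    labels <- vapply(locs, function(l)
      if (is.character(l$labels)) l$labels else NA_character_, "")
  }
  if (is.null(labels) || anyNA(labels) || length(labels) != ncol(data))
    labels <- sprintf("ch%02d", seq_len(ncol(data)))
  colnames(data) <- make.unique(labels)
  sid <- bids_subject_id(path)
  if (is.na(sid)) sid <- sub("\\.[^.]*$", "", basename(path))
  eeg_recording(data, fs = eeg$srate[1], subject_id = sid, units = "uV")
}
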