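# Readers/writers for the supported interchange formats.  BrainVision and
# EDF are import/export paths; the package's canonical container is a small
# HDF5 layout so every downstream stage is format-agnostic.

#' Read an EEG recording
#'
#' Dispatches on `format` (or the file extension): BrainVision header
#' triplets (`.vhdr`), EDF (`.edf`), or the package's HDF5 container
#' (`.h5`/`.hdf5`).
#'
#' @param path file path (for BrainVision, the `.vhdr` file).
#' @param format one of `"auto"`, `"brainvision"`, `"edf"`, `"hdf5"`.
#' @return an [eeg_record] (continuous data with events), or an
#'   [epoched_eeg] if an HDF5 container holds epoched data.
#' @export
read_eeg <- function(path, format = c("auto", "brainvision", "edf", "hdf5")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     vhdr = "brainvision", edf = "edf",
                     h5 = "hdf5", hdf5 = "hdf5",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         brainvision = read_brainvision(path),
         edf = read_edf(path),
         hdf5 = read_eeg_h5(path))
}

## ---------------------------------------------------------------- EDF ----

#' Write an EDF file (16-bit)
#'
#' Minimal EDF writer: a single data record holding the full recording,
#' one int16 stream per channel with per-channel physical scaling.  Event
#' markers are not representable in plain EDF and are dropped with a
#' message; use the HDF5 container to preserve them.
#'
#' @param record an [eeg_record].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  if (length(record$events))
    message("EDF export drops ", length(record$events), " event markers")
  x <- record$data
  ns <- nrow(x); n <- ncol(x)
  pmin_ <- apply(x, 1L, min); pmax_ <- apply(x, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  # header fields are 8 ASCII chars: round the limits outward so the stored
  # text and the scaling used for digitization agree exactly
  pmin_ <- as.numeric(formatC(pmin_ - abs(pmin_) * 1e-5 - 1e-8,
                              format = "g", digits = 6))
  pmax_ <- as.numeric(formatC(pmax_ + abs(pmax_) * 1e-5 + 1e-8,
                              format = "g", digits = 6))
  dmin <- -32768; dmax <- 32767
  pad <- function(s, w) formatC(substr(s, 1L, w), width = w, flag = "-")
  num <- function(v, w) pad(formatC(v, format = "g", digits = 7), w)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X", 80), pad(sprintf("Startdate X %s", "kopmeta"), 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(as.character(256 * (ns + 1)), 8), pad("", 44),
    pad("1", 8), num(n / record$fs, 8), pad(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w) writeChar(paste0(vapply(vals, pad, "", w = w),
                                              collapse = ""), con, eos = NULL)
  field(record$channel_names, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(formatC(pmin_, format = "g", digits = 6), 8)
  field(formatC(pmax_, format = "g", digits = 6), 8)
  field(rep(as.character(dmin), ns), 8)
  field(rep(as.character(dmax), ns), 8)
  field(rep("", ns), 80)
  field(rep(as.character(n), ns), 8)
  field(rep("", ns), 32)
  for (i in seq_len(ns)) {
    dig <- round((x[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) * (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    s <- readChar(con, w, useBytes = TRUE)
    trimws(s)
  }
  version <- rd(8)
  if (version != "0") stop("EDF header field 'version' is '", version,
                           "', expected '0'")
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || ns < 1L) stop("EDF header field 'number of signals' unreadable")
  if (is.na(header_bytes) || header_bytes != 256L * (ns + 1L))
    stop("EDF header field 'header bytes' (", header_bytes,
         ") inconsistent with signal count ", ns)
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (any(is.na(pmin_ + pmax_ + dmin + dmax)))
    stop("EDF header field 'physical/digital min/max' unreadable")
  out <- matrix(0, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- pmin_[i] + (raw - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
      out[i, (r - 1) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  fs <- spr[1] / rec_dur
  eeg_record(out, fs = fs, channel_names = labels)
}

## -------------------------------------------------------- BrainVision ----

#' Write a BrainVision triplet
#'
#' Writes `<stem>.vhdr`, `<stem>.vmrk`, `<stem>.eeg` (IEEE float 32,
#' multiplexed).  Events become `Stimulus,TMS` markers.
#'
#' @param record an [eeg_record].
#' @param stem path without extension.
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(record, stem) {
  stopifnot(inherits(record, "eeg_record"))
  base <- basename(stem)
  vhdr <- paste0(stem, ".vhdr"); vmrk <- paste0(stem, ".vmrk")
  eegf <- paste0(stem, ".eeg")
  ns <- nrow(record$data)
  ch_lines <- sprintf("Ch%d=%s,,1,µV", seq_len(ns), record$channel_names)
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", ns),
    paste0("SamplingInterval=", format(1e6 / record$fs, scientific = FALSE)),
    "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]", ch_lines), vhdr)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]", "Codepage=UTF-8",
          paste0("DataFile=", base, ".eeg"),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0,00000000000000000000")
  if (length(record$events))
    mk <- c(mk, sprintf("Mk%d=Stimulus,TMS,%d,1,0",
                        seq_along(record$events) + 1L, record$events))
  writeLines(mk, vmrk)
  con <- file(eegf, "wb")
  writeBin(as.numeric(record$data), con, size = 4L, endian = "little")
  close(con)
  invisible(vhdr)
}

parse_vhdr_ini <- function(lines) {
  kv <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    m <- regmatches(ln, regexec("^([^=\\[]+)=(.*)$", ln))[[1]]
    if (length(m) == 3L) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  kv
}

read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE, encoding = "UTF-8")
  kv <- parse_vhdr_ini(lines)
  need <- function(k) {
    v <- kv[[k]]
    if (is.null(v)) stop("BrainVision header missing field '", k, "'")
    v
  }
  dirn <- dirname(vhdr_path)
  data_file <- file.path(dirn, need("DataFile"))
  marker_file <- kv[["MarkerFile"]]
  ns <- as.integer(need("NumberOfChannels"))
  fs <- 1e6 / as.numeric(need("SamplingInterval"))
  fmt <- need("BinaryFormat")
  orient <- toupper(need("DataOrientation"))
  if (!file.exists(data_file)) stop("BrainVision DataFile not found: ", data_file)
  ch_keys <- grep("^Ch[0-9]+$", names(kv), value = TRUE)
  ch_keys <- ch_keys[order(as.integer(sub("^Ch", "", ch_keys)))]
  ch_info <- lapply(kv[ch_keys], function(v) strsplit(v, ",")[[1]])
  ch_names <- unname(vapply(ch_info, function(p) p[1], ""))
  resolution <- unname(vapply(ch_info, function(p) {
    r <- suppressWarnings(as.numeric(p[3])); if (is.na(r)) 1 else r
  }, 0))
  sz <- file.size(data_file)
  con <- file(data_file, "rb")
  raw <- switch(fmt,
    IEEE_FLOAT_32 = readBin(con, "numeric", n = sz / 4, size = 4L,
                            endian = "little"),
    INT_16 = readBin(con, "integer", n = sz / 2, size = 2L, signed = TRUE,
                     endian = "little"),
    { close(con); stop("BrainVision field 'BinaryFormat' unsupported: ", fmt) })
  close(con)
  n_samp <- length(raw) %/% ns
  raw <- raw[seq_len(n_samp * ns)]
  x <- if (orient == "MULTIPLEXED") matrix(raw, nrow = ns) else
    t(matrix(raw, ncol = ns))
  x <- x * resolution
  events <- integer()
  if (!is.null(marker_file)) {
    mpath <- file.path(dirn, marker_file)
    if (!file.exists(mpath))
      stop("BrainVision field 'MarkerFile' points to missing file: ", mpath)
    mlines <- readLines(mpath, warn = FALSE, encoding = "UTF-8")
    mkv <- parse_vhdr_ini(mlines)
    ref <- mkv[["DataFile"]]
    if (!is.null(ref) && basename(ref) != basename(data_file))
      stop("marker file field 'DataFile' ('", ref,
           "') does not match header DataFile ('", basename(data_file), "')")
    mk_keys <- grep("^Mk[0-9]+$", names(mkv), value = TRUE)
    mk_keys <- mk_keys[order(as.integer(sub("^Mk", "", mk_keys)))]
    for (k in mk_keys) {
      p <- strsplit(mkv[[k]], ",")[[1]]
      if (length(p) >= 3L && p[1] != "New Segment")
        events <- c(events, as.integer(p[3]))
    }
  }
  eeg_record(x, fs = fs, channel_names = ch_names, events = events)
}

## --------------------------------------------------------------- HDF5 ----

#' Write EEG to the package's HDF5 container
#'
#' Lossless canonical storage for both continuous records and epoched data.
#'
#' @param x an [eeg_record] or [epoched_eeg].
#' @param path output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_eeg_h5 <- function(x, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll())
  if (inherits(x, "eeg_record")) {
    rhdf5::h5write("record", path, "kind")
    rhdf5::h5write(x$data, path, "data")
    rhdf5::h5write(as.integer(x$events), path, "events")
  } else if (inherits(x, "epoched_eeg")) {
    rhdf5::h5write("epoched", path, "kind")
    rhdf5::h5write(x$data, path, "data")
    rhdf5::h5write(as.integer(x$pulse_sample), path, "pulse_sample")
  } else stop("unsupported object")
  rhdf5::h5write(x$fs, path, "fs")
  rhdf5::h5write(x$channel_names, path, "channel_names")
  if (!is.null(x$channel_positions))
    rhdf5::h5write(x$channel_positions, path, "channel_positions")
  sid <- x$subject_id
  rhdf5::h5write(if (is.na(sid)) "" else as.character(sid), path, "subject_id")
  invisible(path)
}

read_eeg_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll())
  ls_ <- rhdf5::h5ls(path)$name
  gv <- function(name) if (name %in% ls_) rhdf5::h5read(path, name) else NULL
  kind <- as.character(gv("kind"))
  pos <- gv("channel_positions")
  subj <- as.character(gv("subject_id"))
  if (identical(kind, "record")) {
    eeg_record(gv("data"), fs = as.numeric(gv("fs")),
               channel_names = as.character(gv("channel_names")),
               events = as.integer(gv("events")),
               channel_positions = pos, subject_id = subj)
  } else if (identical(kind, "epoched")) {
    ps <- gv("pulse_sample")
    epoched_eeg(gv("data"), fs = as.numeric(gv("fs")),
                channel_names = as.character(gv("channel_names")),
                pulse_sample = if (length(ps)) ps else NA_integer_,
                channel_positions = pos, subject_id = subj)
  } else stop("HDF5 container field 'kind' is missing or unknown")
}

## ----------------------------------------------------------- epoching ----

#' Cut a continuous record into pulse-locked epochs
#'
#' Events whose window does not fit in the recording are dropped with a
#' message.  The pulse lands at sample `round(t_pre_ms * fs / 1000) + 1`
#' (1-based) of each epoch.
#'
#' @param record an [eeg_record].
#' @param events event sample indices; default the record's own.
#' @param t_pre_ms,t_post_ms window extent before/after each event, ms
#'   (both positive; total epoch length is their sum).
#' @return an [epoched_eeg].
#' @export
epoch_record <- function(record, events = NULL, t_pre_ms = 500,
                         t_post_ms = 1500) {
  stopifnot(inherits(record, "eeg_record"))
  if (is.null(events)) events <- record$events
  events <- as.integer(events)
  if (!length(events)) stop("no events to epoch around")
  fs <- record$fs
  pre <- round(t_pre_ms * fs / 1000)
  post <- round(t_post_ms * fs / 1000)
  n <- ncol(record$data)
  ok <- (events - pre) >= 1L & (events + post - 1L) <= n
  if (any(!ok))
    message(sum(!ok), " event(s) too close to the record edges; dropped")
  events <- events[ok]
  if (!length(events)) stop("no usable events after edge filtering")
  len <- pre + post
  arr <- array(0, dim = c(length(events), nrow(record$data), len))
  for (e in seq_along(events)) {
    idx <- (events[e] - pre):(events[e] + post - 1L)
    arr[e, , ] <- record$data[, idx]
  }
  epoched_eeg(arr, fs = fs, channel_names = record$channel_names,
              pulse_sample = pre + 1L,
              channel_positions = record$channel_positions,
              subject_id = record$subject_id)
}

## ------------------------------------------------------------- traces ----

#' Write a time-series trace to CSV (+ JSON sidecar)
#'
#' Columns `time_ms`, `value`, plus `epoch` for per-epoch matrices and any
#' metadata columns supplied.  `NaN`/`NA` serialize as empty fields.  A JSON
#' sidecar `<path>.json` records metadata (band, window, seed, ...).
#'
#' @param trace a `meta_trace`/`kop_trace` (see [sliding_metastability()])
#'   or a data.frame with a `time_ms` column.
#' @param path output CSV path.
#' @param meta named list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, meta = list()) {
  if (is.data.frame(trace)) {
    if (!"time_ms" %in% names(trace)) stop("trace has no time axis")
    df <- trace
  } else if (inherits(trace, c("meta_trace", "kop_trace"))) {
    v <- if (inherits(trace, "kop_trace")) trace$r else trace$value
    if (is.matrix(v)) {
      df <- data.frame(
        epoch = rep(seq_len(nrow(v)), each = ncol(v)),
        time_ms = rep(trace$time_ms, times = nrow(v)),
        value = as.vector(t(v)))
    } else {
      df <- data.frame(time_ms = trace$time_ms, value = v)
    }
    for (k in c("band", "group"))
      if (!is.null(trace[[k]])) df[[k]] <- paste(trace[[k]], collapse = "-")
    meta <- c(meta, trace[intersect(names(trace),
                                    c("window_ms", "band", "kind", "channel_set"))])
  } else stop("trace has no time axis")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trace CSV written by [write_trace()]
#' @param path CSV path.
#' @return data.frame (empty fields become `NA`).
#' @export
read_trace <- function(path) {
  utils::read.csv(path, na.strings = c("", "NA", "NaN"))
}
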