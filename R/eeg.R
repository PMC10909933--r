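#' Continuous multichannel EEG record
#'
#' Lightweight container for a continuous recording: a channel-by-sample
#' matrix in microvolts, a sampling rate, and event markers given as sample
#' indices (1-based).
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one per row of `data`.
#' @param events integer vector of event onset sample indices (1-based).
#' @param channel_positions optional numeric matrix (channels x 3), mm.
#' @param subject_id optional label.
#' @return an object of class `eeg_record`.
#' @export
eeg_record <- function(data, fs, channel_names = NULL, events = integer(),
                       channel_positions = NULL, subject_id = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (is.null(channel_names)) channel_names <- sprintf("Ch%02d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", nrow(data), ")")
  events <- as.integer(events)
  if (any(events < 1L | events > ncol(data)))
    stop("events outside the recording")
  if (!is.null(channel_positions)) {
    channel_positions <- as.matrix(channel_positions)
    stopifnot(nrow(channel_positions) == nrow(data), ncol(channel_positions) == 3L)
  }
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 events = events, channel_positions = channel_positions,
                 subject_id = subject_id),
            class = "eeg_record")
}

#' Epoched EEG
#'
#' The pipeline's raw material: an `[epoch x channel x sample]` array in
#' microvolts with sampling rate, channel names, optional 3-D sensor
#' positions, and the sample index of the TMS pulse within each epoch.
#'
#' @param data numeric array `[epoch x channel x sample]`, microvolts.
#' @param fs sampling rate, Hz.
#' @param channel_names character vector matching `dim(data)[2]`.
#' @param pulse_sample 1-based sample index of the pulse within each epoch,
#'   or `NA` for resting (pulse-free) data.
#' @param channel_positions optional channels x 3 matrix, mm.
#' @param subject_id optional label.
#' @return an object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(data, fs, channel_names = NULL, pulse_sample = NA_integer_,
                        channel_positions = NULL, subject_id = NA_character_) {
  if (length(dim(data)) != 3L) stop("data must be a 3-d array [epoch x channel x sample]")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  n_ch <- dim(data)[2]
  n_samp <- dim(data)[3]
  if (is.null(channel_names)) channel_names <- sprintf("Ch%02d", seq_len(n_ch))
  if (length(channel_names) != n_ch)
    stop("channel count (", n_ch, ") does not match channel_names (",
         length(channel_names), ")")
  if (!is.na(pulse_sample)) {
    pulse_sample <- as.integer(pulse_sample)
    if (pulse_sample < 1L || pulse_sample > n_samp)
      stop("pulse_sample outside [1, n_samples]")
  }
  if (!is.null(channel_positions)) {
    channel_positions <- as.matrix(channel_positions)
    stopifnot(nrow(channel_positions) == n_ch, ncol(channel_positions) == 3L)
  }
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 pulse_sample = pulse_sample,
                 channel_positions = channel_positions,
                 subject_id = subject_id),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_eeg> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  if (!is.na(x$pulse_sample))
    cat(sprintf("  pulse at sample %d (%.0f ms)\n", x$pulse_sample,
                1000 * (x$pulse_sample - 1) / x$fs))
  invisible(x)
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs, length(x$events)))
  invisible(x)
}

#' Epoch-relative time axis in milliseconds
#'
#' @param x an `epoched_eeg`, or an integer number of samples.
#' @param fs sampling rate if `x` is a sample count.
#' @return numeric vector, `0` at the first sample.
#' @export
epoch_time_ms <- function(x, fs = NULL) {
  if (inherits(x, "epoched_eeg")) {
    n <- dim(x$data)[3]; fs <- x$fs
  } else {
    n <- as.integer(x)
    if (is.null(fs)) stop("fs required")
  }
  (seq_len(n) - 1) / fs * 1000
}
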