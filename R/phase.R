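# Band-limited instantaneous phase, the Kuramoto order parameter, and its
# sliding-window standard deviation (the package's first metastability
# measure).

#' Band-limited instantaneous phase
#'
#' Zero-phase band-pass filters every channel of every epoch and extracts
#' the analytic-signal angle.  A filter-transient margin of one cycle of the
#' low band edge (capped at a third of the epoch) is flagged in the result
#' (`valid` attribute); phases there are returned but should not enter
#' window statistics that demand clean data.
#'
#' @param eeg an [epoched_eeg].
#' @param band length-2 numeric (low, high), Hz; must lie in (0, fs/2).
#' @return object of class `phase_tensor`: list with `phase`
#'   (`[epoch x channel x sample]`, radians in (-pi, pi]), `band`, `fs`,
#'   `valid` (first/last trustworthy sample), and `envelope`
#'   (analytic amplitude, same shape).
#' @export
extract_phase <- function(eeg, band) {
  stopifnot(inherits(eeg, "epoched_eeg"))
  if (band[2] >= eeg$fs / 2) stop("band edge ", band[2],
                                  " Hz at or above Nyquist")
  d <- dim(eeg$data)
  ph <- array(NA_real_, d)
  env <- array(NA_real_, d)
  for (e in seq_len(d[1])) {
    filt <- bandpass_filter(eeg$data[e, , ], band, eeg$fs)
    a <- analytic_signal(filt)
    ph[e, , ] <- Arg(a)
    env[e, , ] <- Mod(a)
  }
  margin <- min(round(eeg$fs / band[1]), floor(d[3] / 3))
  structure(list(phase = ph, envelope = env, band = band, fs = eeg$fs,
                 valid = c(margin + 1L, d[3] - margin),
                 channel_names = eeg$channel_names,
                 pulse_sample = eeg$pulse_sample),
            class = "phase_tensor")
}

#' Kuramoto order parameter
#'
#' For each epoch and time point, `r e^{i psi} = (1/N) sum_j e^{i theta_j}`
#' over the chosen channel set: `r` is the modulus (1 = full synchrony,
#' 0 = uniform desynchronization), `psi` the mean phase angle.
#'
#' @param phases a `phase_tensor` from [extract_phase()], or a numeric
#'   vector/matrix of phases (vector = one time slice over channels;
#'   matrix = channels x samples).
#' @param channels channel indices or names to include (default all);
#'   at least 2.
#' @return for array input, object of class `kop_trace` with `r` and `psi`
#'   (`[epoch x sample]`), `time_ms`, `fs`, `channel_set`; for a vector,
#'   a list with scalar `r` and `psi`.
#' @export
kop <- function(phases, channels = NULL) {
  if (is.numeric(phases) && is.null(dim(phases))) {
    if (length(phases) < 2L) stop("need at least 2 channels")
    z <- mean(exp(1i * phases))
    return(list(r = Mod(z), psi = Arg(z)))
  }
  if (is.matrix(phases)) {
    if (nrow(phases) < 2L) stop("need at least 2 channels")
    z <- colMeans(exp(1i * phases))
    return(list(r = Mod(z), psi = Arg(z)))
  }
  stopifnot(inherits(phases, "phase_tensor"))
  d <- dim(phases$phase)
  idx <- resolve_channels(channels, phases$channel_names)
  if (length(idx) < 2L) stop("need at least 2 channels")
  z <- exp(1i * phases$phase[, idx, , drop = FALSE])
  zsum <- apply(z, c(1, 3), mean)   # [epoch x sample] complex
  structure(list(r = Mod(zsum), psi = Arg(zsum),
                 channel_set = phases$channel_names[idx],
                 fs = phases$fs, band = phases$band,
                 time_ms = (seq_len(d[3]) - 1) / phases$fs * 1000,
                 valid = phases$valid,
                 pulse_sample = phases$pulse_sample),
            class = "kop_trace")
}

resolve_channels <- function(channels, names_) {
  if (is.null(channels)) return(seq_along(names_))
  if (is.character(channels)) {
    idx <- match(channels, names_)
    if (anyNA(idx)) stop("unknown channel(s): ",
                         paste(channels[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(channels)
}

#' Sliding-window metastability (std of the KOP)
#'
#' Population standard deviation of `r(t)` in a centered sliding window
#' (default 50 ms, stride 1 sample); positions without full window support
#' are `NaN`.  This windowed variability of synchrony is the operational
#' metastability measure.
#'
#' @param kop_trace a `kop_trace`, or a numeric vector/matrix of `r` values
#'   (rows = epochs) with `fs` supplied.
#' @param window_ms window length, ms.
#' @param stride stride in samples (default 1 = dense).
#' @param fs sampling rate when `kop_trace` is raw numeric.
#' @return object of class `meta_trace`: `value` (`[epoch x position]` or
#'   vector), `time_ms`, `window_ms`, `band`.
#' @export
sliding_metastability <- function(kop_trace, window_ms = 50, stride = 1L,
                                  fs = NULL) {
  if (inherits(kop_trace, "kop_trace")) {
    r <- kop_trace$r; fs <- kop_trace$fs
    band <- kop_trace$band; tm <- kop_trace$time_ms
    pulse <- kop_trace$pulse_sample
  } else {
    r <- kop_trace; band <- NULL; pulse <- NA_integer_
    if (is.null(fs)) stop("fs required for raw input")
    n <- if (is.matrix(r)) ncol(r) else length(r)
    tm <- (seq_len(n) - 1) / fs * 1000
  }
  if (is.null(dim(r))) r <- matrix(r, nrow = 1L)
  w <- round(window_ms * fs / 1000)
  if (w < 2L) stop("window must span at least 2 samples")
  if (w > ncol(r)) stop("window (", w, " samples) longer than trace (",
                        ncol(r), ")")
  val <- t(apply(r, 1L, windowed_pop_sd, w = w))
  keep <- seq(1L, ncol(r), by = as.integer(stride))
  out_val <- val[, keep, drop = FALSE]
  if (nrow(out_val) == 1L) out_val <- drop(out_val)
  structure(list(value = out_val, time_ms = tm[keep], window_ms = window_ms,
                 stride = as.integer(stride), band = band,
                 pulse_sample = pulse, fs = fs, kind = "kop_std"),
            class = "meta_trace")
}

# population sd in centered windows of length w over a vector; NaN where the
# full window does not fit.  Window at position i covers
# [i - floor(w/2), i + ceiling(w/2) - 1].
windowed_pop_sd <- function(x, w) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  m <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  m2 <- (cs2[(w + 1):(n + 1)] - cs2[1:(n - w + 1)]) / w
  v <- pmax(m2 - m^2, 0)
  out <- rep(NaN, n)
  lo <- floor(w / 2)
  out[(lo + 1):(lo + length(m))] <- sqrt(v)
  out
}

#' Normalize a trace to percent of a baseline interval
#'
#' @param trace a `meta_trace`/`kop_trace` or numeric vector.
#' @param baseline_interval_ms length-2 interval, epoch-relative ms.
#' @param time_ms time axis when `trace` is a bare vector.
#' @return same shape as the input with values in percent of the baseline
#'   mean; for trace objects the normalized values are stored in
#'   `baseline_pct` alongside the raw `value`.
#' @export
baseline_normalize <- function(trace, baseline_interval_ms = c(525, 1525),
                               time_ms = NULL) {
  if (is.numeric(trace) && is.null(dim(trace))) {
    if (is.null(time_ms)) stop("time_ms required for raw input")
    sel <- time_ms >= baseline_interval_ms[1] & time_ms <= baseline_interval_ms[2]
    if (!any(sel)) stop("baseline interval outside trace support")
    b <- mean(trace[sel], na.rm = TRUE)
    if (!is.finite(b) || b == 0) stop("baseline mean is zero or undefined")
    return(100 * trace / b)
  }
  v <- if (inherits(trace, "kop_trace")) trace$r else trace$value
  tm <- trace$time_ms
  sel <- tm >= baseline_interval_ms[1] & tm <= baseline_interval_ms[2]
  if (!any(sel)) stop("baseline interval outside trace support")
  vm <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  b <- mean(vm[, sel], na.rm = TRUE)
  if (!is.finite(b) || b == 0) stop("baseline mean is zero or undefined")
  pct <- 100 * v / b
  trace$baseline_pct <- pct
  trace$baseline_interval_ms <- baseline_interval_ms
  trace
}

#' Average traces across epochs or subjects
#'
#' Pointwise mean ignoring `NaN` margins; the per-point contributing count
#' is recorded.
#'
#' @param traces a `meta_trace`/`kop_trace` with per-epoch matrix values, a
#'   numeric matrix (rows averaged), or a list of aligned traces/vectors.
#' @return for objects: the same object with `value` collapsed to a vector
#'   and an `n` field; for matrices/lists: list with `value` and `n`.
#' @export
average_over <- function(traces) {
  collapse <- function(m) {
    n_pt <- colSums(!is.na(m))
    v <- colMeans(m, na.rm = TRUE)
    v[n_pt == 0L] <- NaN
    list(value = v, n = n_pt)
  }
  if (inherits(traces, c("meta_trace", "kop_trace"))) {
    v <- if (inherits(traces, "kop_trace")) traces$r else traces$value
    if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
    cz <- collapse(v)
    if (inherits(traces, "kop_trace")) traces$r <- cz$value else
      traces$value <- cz$value
    traces$n <- cz$n
    return(traces)
  }
  if (is.matrix(traces)) return(collapse(traces))
  if (is.list(traces)) {
    vecs <- lapply(traces, function(t) {
      v <- if (inherits(t, c("meta_trace", "kop_trace"))) {
        if (inherits(t, "kop_trace")) t$r else t$value
      } else t
      if (!is.null(dim(v))) stop("list elements must be vector traces; ",
                                 "average epochs first")
      v
    })
    lens <- vapply(vecs, length, 0L)
    if (length(unique(lens)) != 1L) stop("traces have mismatched lengths")
    return(collapse(do.call(rbind, vecs)))
  }
  stop("unsupported input")
}
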