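# Channel grouping from the TMS-evoked potential: find the moment of
# maximal topographic spread (GFP peak) after the pulse, rank channels by
# their deviation from the grand mean there, and split off the top and
# bottom tertiles.

#' Grand-average evoked response
#'
#' Averages across epochs; with a list of subjects' epoched data, the
#' per-subject averages are averaged again (grand average).
#'
#' @param eeg an [epoched_eeg] or a list of them (one per subject).
#' @return matrix channels x samples with attributes `fs`, `pulse_sample`,
#'   `channel_names`.
#' @export
evoked_response <- function(eeg) {
  if (inherits(eeg, "epoched_eeg")) eeg <- list(eeg)
  stopifnot(length(eeg) >= 1L, all(vapply(eeg, inherits, TRUE, "epoched_eeg")))
  per_subj <- lapply(eeg, function(x) apply(x$data, c(2, 3), mean))
  erp <- Reduce(`+`, per_subj) / length(per_subj)
  attr(erp, "fs") <- eeg[[1]]$fs
  attr(erp, "pulse_sample") <- eeg[[1]]$pulse_sample
  attr(erp, "channel_names") <- eeg[[1]]$channel_names
  rownames(erp) <- eeg[[1]]$channel_names
  erp
}

#' Global field power
#'
#' Per-sample population standard deviation across channels — the spatial
#' spread of the instantaneous topography.
#'
#' @param x numeric matrix channels x samples (or a single column map).
#' @return numeric vector, one value per sample.
#' @export
global_field_power <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("GFP needs at least 2 channels")
  mu <- colMeans(x)
  sqrt(colMeans(x^2) - mu^2)
}

#' Derive channel groups from an evoked response
#'
#' Finds the sample with the highest GFP inside a post-pulse search window,
#' subtracts the grand mean across channels from each channel's value
#' there, sorts the differences ascending, and assigns the bottom and top
#' `floor(n/3)` channels to two groups.  Exact ties in the differences are
#' resolved by channel order; tied GFP maxima take the earliest sample.
#'
#' @param erp channels x samples matrix from [evoked_response()].
#' @param fs sampling rate; default from the `fs` attribute.
#' @param pulse_sample pulse index; default from the attribute.  If `NA`,
#'   the whole trace is searched.
#' @param search_window_ms post-pulse window searched for the GFP peak
#'   (default 10-300 ms) so the pulse-sample discontinuity itself cannot
#'   be selected.
#' @param channel_names labels; default from the attribute or rownames.
#' @return object of class `channel_grouping`: `group_top`, `group_bottom`
#'   (labels), `gfp_peak_sample`, `gfp_peak_ms`, `mean_differences`.
#' @export
group_channels <- function(erp, fs = attr(erp, "fs"),
                           pulse_sample = attr(erp, "pulse_sample"),
                           search_window_ms = c(10, 300),
                           channel_names = NULL) {
  erp <- as.matrix(erp)
  n_ch <- nrow(erp)
  if (n_ch < 3L) stop("need at least 3 channels to form tertiles")
  if (is.null(channel_names))
    channel_names <- attr(erp, "channel_names")
  if (is.null(channel_names)) channel_names <- rownames(erp)
  if (is.null(channel_names)) channel_names <- sprintf("Ch%02d", seq_len(n_ch))
  gfp <- global_field_power(erp)
  idx <- seq_len(ncol(erp))
  if (!is.null(pulse_sample) && !is.na(pulse_sample) && !is.null(fs)) {
    lo <- pulse_sample + round(search_window_ms[1] * fs / 1000)
    hi <- pulse_sample + round(search_window_ms[2] * fs / 1000)
    idx <- idx[idx >= lo & idx <= min(hi, ncol(erp))]
    if (!length(idx)) stop("search window outside the epoch")
  }
  peak <- idx[which.max(gfp[idx])]   # which.max -> earliest tie
  diffs <- erp[, peak] - mean(erp[, peak])
  names(diffs) <- channel_names
  if (all(abs(diffs) < .Machine$double.eps * 100))
    stop("constant topography at the GFP peak: all mean differences are ",
         "zero, so tertiles are undefined; supply a tie policy or check data")
  g <- floor(n_ch / 3)
  ord <- order(diffs, seq_len(n_ch))   # stable: ties by channel order
  structure(list(group_bottom = channel_names[ord[seq_len(g)]],
                 group_top = channel_names[ord[(n_ch - g + 1):n_ch]],
                 gfp_peak_sample = peak,
                 gfp_peak_ms = if (!is.null(fs)) (peak - 1) / fs * 1000 else NA,
                 mean_differences = diffs),
            class = "channel_grouping")
}

#' @export
print.channel_grouping <- function(x, ...) {
  cat(sprintf("<channel_grouping> GFP peak at sample %d (%.0f ms)\n",
              x$gfp_peak_sample, x$gfp_peak_ms))
  cat("  top:    ", paste(x$group_top, collapse = " "), "\n")
  cat("  bottom: ", paste(x$group_bottom, collapse = " "), "\n")
  invisible(x)
}
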