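# Lempel-Ziv (LZ76) complexity of symbolic sequences: the number of
# phrases in the exhaustive-history parsing, i.e. the minimum number of
# unique substrings that can be copied and combined to reproduce the
# original sequence.

#' Lempel-Ziv (LZ76) complexity
#'
#' @param symbols vector over a finite alphabet (integer, character or
#'   factor); nonempty.
#' @return integer phrase count.  Invariant under alphabet relabeling and
#'   non-decreasing under sequence extension.
#' @examples
#' lempel_ziv_complexity(c("a","a","a","a","a","a","a","a"))  # 2
#' @export
lempel_ziv_complexity <- function(symbols) {
  if (!length(symbols)) stop("empty sequence")
  codes <- as.integer(factor(symbols, levels = unique(symbols)))
  lz76_cpp(codes)
}

#' Windowed Lempel-Ziv complexity of a label sequence
#'
#' Computes the LZ76 phrase count in windows of `window_ms`.  In `"tiled"`
#' mode (default) the windows partition the sequence into consecutive bins;
#' in `"sliding"` mode a dense centered window runs at every sample and
#' positions without full support are `NaN`.
#'
#' @param labels integer vector, `label_sequence`, or matrix (rows =
#'   epochs).
#' @param window_ms window length, ms.
#' @param fs sampling rate (taken from a `label_sequence` if given).
#' @param mode `"tiled"` or `"sliding"`.
#' @return object of class `meta_trace` (kind `"lzc"`): `value` (vector or
#'   epochs x position matrix), `time_ms` (bin/window centers).
#' @export
sliding_lzc <- function(labels, window_ms = 100, fs = NULL,
                        mode = c("tiled", "sliding")) {
  mode <- match.arg(mode)
  pulse <- NA_integer_
  if (inherits(labels, "label_sequence")) {
    if (is.null(fs)) fs <- labels$fs
    pulse <- labels$pulse_sample
    labels <- labels$labels
  }
  if (is.null(fs) || is.na(fs)) stop("fs required")
  lm <- if (is.matrix(labels)) labels else matrix(labels, nrow = 1L)
  n <- ncol(lm)
  w <- round(window_ms * fs / 1000)
  if (w < 2L) stop("window must span at least 2 samples")
  if (w > n) stop("window (", w, " samples) longer than sequence (", n, ")")
  if (mode == "tiled") {
    n_bin <- n %/% w
    starts <- (seq_len(n_bin) - 1L) * w + 1L
    val <- t(apply(lm, 1L, function(s)
      vapply(starts, function(a) lz76_cpp(as.integer(s[a:(a + w - 1L)])), 0L)))
    tm <- (starts - 1 + (w - 1) / 2) / fs * 1000
  } else {
    lo <- floor(w / 2)
    pos_start <- lo + 1L
    pos_end <- n - (w - 1L - lo)
    val <- t(apply(lm, 1L, function(s) {
      out <- rep(NaN, n)
      for (i in pos_start:pos_end) {
        a <- i - lo
        out[i] <- lz76_cpp(as.integer(s[a:(a + w - 1L)]))
      }
      out
    }))
    tm <- (seq_len(n) - 1) / fs * 1000
  }
  if (nrow(val) == 1L) val <- drop(val)
  structure(list(value = val, time_ms = tm, window_ms = window_ms,
                 mode = mode, fs = fs, pulse_sample = pulse, kind = "lzc"),
            class = "meta_trace")
}
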