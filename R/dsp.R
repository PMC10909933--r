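# Signal-processing primitives: zero-phase band-pass and analytic signal.
# No FIR design package is assumed; filtering is done in the frequency
# domain with raised-cosine transition bands, which is zero-phase by
# construction and equivalent to a symmetric kernel as long as the epoch.

#' Zero-phase band-pass filter
#'
#' Filters each row of `x` with a frequency-domain mask: unit gain inside
#' `band`, zero far outside, raised-cosine transitions of width
#' `transition_frac` times each band edge.  The signal is mirror-padded by
#' half its length to suppress wrap-around transients.
#'
#' @param x numeric vector or matrix (rows = channels/signals).
#' @param band length-2 numeric, (low, high) in Hz; both in (0, fs/2).
#' @param fs sampling rate, Hz.
#' @param transition_frac transition width as a fraction of each band edge.
#' @return filtered object with the shape of `x`.
#' @export
bandpass_filter <- function(x, band, fs, transition_frac = 0.25) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("band must be increasing and positive")
  if (band[2] >= fs / 2) stop("band edge ", band[2], " Hz at or above Nyquist (",
                              fs / 2, " Hz)")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  n <- ncol(xm)
  pad <- ceiling(n / 2)
  idx_pre <- rev(seq_len(pad) + 1L)      # mirror without repeating the edge
  idx_post <- n - seq_len(pad)
  xp <- cbind(xm[, idx_pre, drop = FALSE], xm, xm[, idx_post, drop = FALSE])
  np <- ncol(xp)
  freqs <- (seq_len(np) - 1) / np * fs
  freqs <- pmin(freqs, fs - freqs)       # two-sided magnitude axis
  tw1 <- transition_frac * band[1]
  tw2 <- transition_frac * band[2]
  gain <- raised_cosine_gain(freqs, band[1], band[2], tw1, tw2)
  ft <- t(apply(xp, 1L, fft))
  filt <- t(apply(ft * rep(gain, each = nrow(xp)), 1L,
                  function(z) Re(fft(z, inverse = TRUE)) / np))
  out <- filt[, pad + seq_len(n), drop = FALSE]
  if (vec) drop(out) else out
}

raised_cosine_gain <- function(f, lo, hi, tw_lo, tw_hi) {
  g <- numeric(length(f))
  g[f >= lo & f <= hi] <- 1
  rise <- f >= (lo - tw_lo) & f < lo
  g[rise] <- 0.5 * (1 + cos(pi * (lo - f[rise]) / tw_lo))
  fall <- f > hi & f <= (hi + tw_hi)
  g[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / tw_hi))
  g
}

#' Analytic signal via FFT
#'
#' @param x numeric vector or matrix (rows are signals).
#' @return complex object shaped like `x`; `Arg()` of it is the
#'   instantaneous phase, `Mod()` the envelope.
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  n <- ncol(xm)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  out <- t(apply(xm, 1L, function(row) fft(fft(row) * h, inverse = TRUE) / n))
  if (vec) drop(out) else out
}

#' Centered moving average
#'
#' @param x numeric vector.
#' @param w window length in samples (>= 1).
#' @return vector like `x`; positions without full support are `NA`.
#' @export
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w < 1L) stop("window must be >= 1 sample")
  n <- length(x)
  if (w > n) stop("window longer than signal")
  cs <- cumsum(c(0, x))
  means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  out <- rep(NA_real_, n)
  lo <- floor(w / 2)
  out[(lo + 1):(lo + length(means))] <- means
  out
}

# Local minima of a vector with a simple prominence rule: a minimum at i
# qualifies if on both sides the trace rises at least `min_prom` above x[i]
# before falling below x[i] again.  Plateaus take their first index.
local_minima <- function(x, min_prom = 0) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) > 0) + 1L
  if (!length(cand)) return(integer())
  keep <- vapply(cand, function(i) {
    v <- x[i]
    lp <- 0
    for (j in seq(i - 1L, 1L)) {
      if (x[j] < v) break
      lp <- max(lp, x[j] - v)
    }
    rp <- 0
    if (i < n) for (j in seq(i + 1L, n)) {
      if (x[j] < v) break
      rp <- max(rp, x[j] - v)
    }
    min(lp, rp) >= min_prom
  }, logical(1))
  cand[keep]
}
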