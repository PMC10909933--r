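# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive implementations in a different style (string search,
# brute-force loops, full enumeration) from the package's own code paths.

# LZ76 oracle: exhaustive-history parsing via literal substring search on
# collapsed strings.  A phrase grows while the candidate occurs inside the
# prefix ending one symbol before the candidate's end.
lz76_oracle <- function(symbols) {
  s <- as.character(symbols)
  n <- length(s)
  stopifnot(n >= 1)
  c_cnt <- 1L
  p <- 2L
  while (p <= n) {
    l <- 1L
    repeat {
      if (p + l - 1L > n) break
      cand <- paste(s[p:(p + l - 1L)], collapse = "\x01")
      hist <- paste(s[1:(p + l - 2L)], collapse = "\x01")
      if (!grepl(cand, hist, fixed = TRUE)) break
      l <- l + 1L
    }
    c_cnt <- c_cnt + 1L
    if (p + l - 1L > n) break
    p <- p + l
  }
  c_cnt
}

# brute-force centered-window population std (matches sliding_metastability
# placement: window at i covers [i - floor(w/2), i + ceiling(w/2) - 1])
windowed_sd_oracle <- function(x, w) {
  n <- length(x)
  out <- rep(NaN, n)
  lo <- floor(w / 2)
  for (i in seq_len(n)) {
    a <- i - lo; b <- a + w - 1L
    if (a >= 1 && b <= n) {
      seg <- x[a:b]
      out[i] <- sqrt(mean((seg - mean(seg))^2))
    }
  }
  out
}

# exact one-tailed Wilcoxon signed-rank p by enumerating all 2^n sign
# patterns (midranks for ties)
wilcoxon_enum_oracle <- function(pre, post, direction) {
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  T_obs <- sum(rk[d > 0])
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Ts <- apply(grid, 1L, function(sel) sum(rk[unlist(sel)]))
  p <- if (direction == "less") mean(Ts <= T_obs + 1e-9)
       else mean(Ts >= T_obs - 1e-9)
  list(T = T_obs, p = p)
}

# tiny epoched fixture: deterministic sinusoids + optional noise
make_sine_epochs <- function(n_epochs = 2, n_ch = 4, n_samp = 1000,
                             fs = 1000, freq = 10, noise = 0, seed = 1) {
  set.seed(seed)
  arr <- array(0, c(n_epochs, n_ch, n_samp))
  t <- (seq_len(n_samp) - 1) / fs
  for (e in seq_len(n_epochs))
    for (c in seq_len(n_ch))
      arr[e, c, ] <- sin(2 * pi * freq * t + 0.3 * c) +
        noise * rnorm(n_samp)
  epoched_eeg(arr, fs = fs, pulse_sample = n_samp %/% 2)
}
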