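# Pre/post window statistics: per-subject window means, a normality
# annotation, and one-tailed Wilcoxon signed-rank tests (exact null by
# enumeration for small n, midrank tie handling).

#' Pre/post (and reference) window means of a trace
#'
#' `pre` is the NaN-ignoring mean over `[pulse - window, pulse)`, `post`
#' over `(pulse, pulse + window]`.  A reference window of the same length
#' at the start of the trace's non-NaN support is also returned; it serves
#' as the comparator for "increase before the pulse" effects.
#'
#' @param trace `meta_trace`/`kop_trace` (vector-valued; average epochs
#'   first) or numeric vector with `time_ms`.
#' @param pulse_ms pulse time, epoch-relative ms (default from the trace).
#' @param window_ms window length (default 250 ms).
#' @param time_ms time axis for raw input.
#' @return list with `pre`, `post`, `ref`, and the contributing sample
#'   counts `n_pre`, `n_post`, `n_ref`.
#' @export
prepost_means <- function(trace, pulse_ms = NULL, window_ms = 250,
                          time_ms = NULL) {
  if (inherits(trace, c("meta_trace", "kop_trace"))) {
    v <- if (inherits(trace, "kop_trace")) trace$r else trace$value
    if (is.matrix(v)) stop("per-epoch matrix trace: run average_over() first")
    time_ms <- trace$time_ms
    if (is.null(pulse_ms)) {
      if (is.na(trace$pulse_sample)) stop("trace has no pulse time")
      pulse_ms <- (trace$pulse_sample - 1) / trace$fs * 1000
    }
  } else {
    v <- trace
    if (is.null(time_ms) || is.null(pulse_ms)) stop("time_ms and pulse_ms required")
  }
  if (min(time_ms) > pulse_ms - window_ms ||
      max(time_ms) < pulse_ms + window_ms)
    stop("pre/post windows exceed trace support")
  pre_sel <- time_ms >= (pulse_ms - window_ms) & time_ms < pulse_ms
  post_sel <- time_ms > pulse_ms & time_ms <= (pulse_ms + window_ms)
  supp <- which(!is.na(v))
  if (!length(supp)) stop("trace is all NaN")
  t0 <- time_ms[supp[1]]
  ref_sel <- time_ms >= t0 & time_ms < t0 + window_ms
  mean_n <- function(sel) {
    x <- v[sel]; x <- x[!is.na(x)]
    if (!length(x)) stop("window contains no finite values")
    list(m = mean(x), n = length(x))
  }
  pre <- mean_n(pre_sel); post <- mean_n(post_sel); ref <- mean_n(ref_sel)
  list(pre = pre$m, post = post$m, ref = ref$m,
       n_pre = pre$n, n_post = post$n, n_ref = ref$n)
}

#' Per-subject pre/post table
#'
#' @param traces list of vector-valued traces, one per subject.
#' @param pulse_ms,window_ms passed to [prepost_means()].
#' @param measure,band,group metadata labels attached to the table.
#' @return data.frame (class `prepost_table`) with columns `subject`,
#'   `pre`, `post`, `ref`.
#' @export
prepost_table <- function(traces, pulse_ms = NULL, window_ms = 250,
                          measure = "metastability", band = NA, group = NA) {
  rows <- lapply(traces, prepost_means, pulse_ms = pulse_ms,
                 window_ms = window_ms)
  df <- data.frame(subject = seq_along(rows),
                   pre = vapply(rows, `[[`, 0, "pre"),
                   post = vapply(rows, `[[`, 0, "post"),
                   ref = vapply(rows, `[[`, 0, "ref"))
  if (any(!complete.cases(df))) stop("NaN pre/post pair")
  attr(df, "measure") <- measure
  attr(df, "band") <- if (is.numeric(band)) paste(band, collapse = "-") else band
  attr(df, "group") <- group
  class(df) <- c("prepost_table", class(df))
  df
}

#' Shapiro-Wilk normality annotation
#'
#' Thin wrapper used only to annotate output; the pipeline always proceeds
#' non-parametrically regardless of the result.
#'
#' @param values numeric, 3 <= n.
#' @return list `W`, `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) stop("Shapiro-Wilk needs n >= 3")
  if (diff(range(values)) < .Machine$double.eps * 100)
    stop("constant input: Shapiro-Wilk undefined")
  r <- stats::shapiro.test(values)
  list(W = unname(r$statistic), p = r$p.value)
}

#' One-tailed Wilcoxon signed-rank test for paired samples
#'
#' The statistic is `T = W+`, the sum of the midranks of `|post - pre|`
#' over pairs with `post > pre`; zero differences are dropped (Wilcoxon's
#' original treatment).  For `n <= 25` retained pairs the p-value is exact,
#' from the full null distribution of `W+` (shift algorithm over doubled
#' midranks, valid under ties); above that, a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param pre,post paired numeric vectors.
#' @param direction alternative about `post` relative to `pre`:
#'   `"less"` (post < pre) or `"greater"`.
#' @return list with `T`, `p`, `n` (pairs retained), `exact` flag.
#' @export
wilcoxon_signed_rank <- function(pre, post, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(pre) == length(post))
  d <- post - pre
  d <- d[!is.na(d)]
  d <- d[abs(d) > 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  if (n < 5L) stop("fewer than 5 nonzero differences (n = ", n, ")")
  rk <- rank(abs(d))                       # midranks
  T_plus <- sum(rk[d > 0])
  if (n <= 25L) {
    r2 <- as.integer(round(2 * rk))        # doubled midranks are integers
    total <- sum(r2)
    counts <- numeric(total + 1)           # index = 2*W+ + 1
    counts[1] <- 1
    for (r in r2) {
      shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
      counts <- counts + shifted
    }
    t2 <- round(2 * T_plus)
    p_le <- sum(counts[seq_len(t2 + 1)]) / 2^n
    p_ge <- sum(counts[(t2 + 1):(total + 1)]) / 2^n
    p <- if (direction == "less") p_le else p_ge
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sigma <- sqrt(sigma2)
    p <- if (direction == "less")
      pnorm((T_plus - mu + 0.5) / sigma)
    else
      pnorm((T_plus - mu - 0.5) / sigma, lower.tail = FALSE)
    exact <- FALSE
  }
  list(T = T_plus, p = min(max(p, 0), 1), n = n, exact = exact,
       direction = direction)
}

#' Run the full battery of pre/post significance tests
#'
#' For each supplied table the three directional effects are tested:
#' decrease after the pulse (post < pre), increase before the pulse (pre >
#' reference window), and increase after the pulse (post > pre).  Raw
#' p-values are reported (matching the presentation of the original
#' analysis) alongside a Holm-corrected column; a Shapiro-Wilk annotation
#' of the paired differences is attached.
#'
#' @param tables a `prepost_table` or list of them (e.g. one per band x
#'   measure x channel group).
#' @param alpha significance threshold (default 0.05).
#' @param effects subset of
#'   `c("decrease_after", "increase_before", "increase_after")`.
#' @return data.frame: `measure`, `band`, `group`, `effect`, `n`, `T`,
#'   `p`, `significant`, `p_holm`, `shapiro_p`.
#' @export
run_stats_battery <- function(tables, alpha = 0.05,
                              effects = c("decrease_after", "increase_before",
                                          "increase_after")) {
  if (inherits(tables, "prepost_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  rows <- list()
  for (tb in tables) {
    for (eff in effects) {
      res <- switch(eff,
        decrease_after = wilcoxon_signed_rank(tb$pre, tb$post, "less"),
        increase_after = wilcoxon_signed_rank(tb$pre, tb$post, "greater"),
        increase_before = wilcoxon_signed_rank(tb$ref, tb$pre, "greater"))
      sw <- tryCatch(shapiro_wilk(tb$post - tb$pre)$p,
                     error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = attr(tb, "measure") %||% NA, band = attr(tb, "band") %||% NA,
        group = attr(tb, "group") %||% NA, effect = eff, n = res$n,
        T = res$T, p = res$p, shapiro_p = sw)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
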