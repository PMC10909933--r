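#' Default frequency bands (Hz)
#'
#' Only the alpha band (8-12 Hz) is fixed by the analysis design; the other
#' edges follow EEG convention and can be overridden in the config.
#' @return named list of length-2 numeric vectors.
#' @export
default_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 45))
}

#' Analysis configuration
#'
#' Bundles the tunable windows of the pipeline.  Defaults: 50 ms sliding
#' window for KOP standard deviation, 100 ms window for Lempel-Ziv
#' complexity, 250 ms pre/post comparison windows, baseline normalization
#' interval 525-1525 ms (epoch-relative), alpha level 0.05.
#'
#' @param bands named list of frequency intervals in Hz.
#' @param metastability_window_ms sliding window for the KOP std, ms.
#' @param lzc_window_ms window for sliding/tiled LZC, ms.
#' @param prepost_window_ms pre/post comparison window, ms.
#' @param baseline_interval_ms length-2, baseline interval, ms.
#' @param alpha_level significance threshold.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(bands = default_bands(),
                            metastability_window_ms = 50,
                            lzc_window_ms = 100,
                            prepost_window_ms = 250,
                            baseline_interval_ms = c(525, 1525),
                            alpha_level = 0.05) {
  stopifnot(metastability_window_ms > 0, lzc_window_ms > 0,
            prepost_window_ms > 0, length(baseline_interval_ms) == 2L,
            baseline_interval_ms[2] > baseline_interval_ms[1],
            alpha_level > 0, alpha_level < 1)
  for (b in bands) {
    if (length(b) != 2L || b[2] <= b[1] || b[1] <= 0)
      stop("band edges must be positive and increasing")
  }
  structure(list(bands = bands,
                 metastability_window_ms = metastability_window_ms,
                 lzc_window_ms = lzc_window_ms,
                 prepost_window_ms = prepost_window_ms,
                 baseline_interval_ms = baseline_interval_ms,
                 alpha_level = alpha_level),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file; keys as in [analysis_config()].
#' @return `analysis_config`
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$bands))
    args$bands <- lapply(raw$bands, function(b) as.numeric(unlist(b)))
  for (k in c("metastability_window_ms", "lzc_window_ms", "prepost_window_ms",
              "alpha_level"))
    if (!is.null(raw[[k]])) args[[k]] <- as.numeric(raw[[k]])
  if (!is.null(raw$baseline_interval_ms))
    args$baseline_interval_ms <- as.numeric(unlist(raw$baseline_interval_ms))
  do.call(analysis_config, args)
}
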