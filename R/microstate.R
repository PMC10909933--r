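# EEG microstates: GFP-peak map extraction, TAAHC clustering,
# Krzanowski-Lai model selection, backfitting and transition statistics.
# Spatial correlation is polarity-invariant (absolute value) throughout,
# the standard convention for microstate maps.

# center (average-reference) and unit-norm map rows; zero-variance rows
# flagged with NA norm
normalize_maps <- function(m) {
  m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(m^2))
  bad <- nrm < .Machine$double.eps * 100
  nrm[bad] <- NA_real_
  list(maps = m / nrm, bad = bad)
}

#' Extract topographic maps at GFP peaks
#'
#' Local maxima of the global field power (strictly above both neighboring
#' distinct values; plateaus contribute their first sample).  For epoched
#' data, peaks are collected per epoch.
#'
#' @param eeg an [epoched_eeg] or a channels x samples matrix.
#' @param max_maps optional cap on the number of maps returned (evenly
#'   subsampled) to bound clustering cost.
#' @return matrix `n_peaks x n_channels` of maps at the peak samples,
#'   with attribute `peak_index`.
#' @export
gfp_peaks <- function(eeg, max_maps = Inf) {
  mats <- if (inherits(eeg, "epoched_eeg")) {
    lapply(seq_len(dim(eeg$data)[1]), function(e) eeg$data[e, , ])
  } else list(as.matrix(eeg))
  maps <- list(); idx_all <- integer()
  for (m in mats) {
    if (ncol(m) < 3L) stop("need at least 3 samples")
    g <- global_field_power(m)
    pk <- plateau_maxima(g)
    if (length(pk)) {
      maps[[length(maps) + 1L]] <- t(m[, pk, drop = FALSE])
      idx_all <- c(idx_all, pk)
    }
  }
  if (!length(maps)) stop("no GFP peaks found")
  out <- do.call(rbind, maps)
  if (nrow(out) > max_maps) {
    keep <- round(seq(1L, nrow(out), length.out = max_maps))
    out <- out[keep, , drop = FALSE]
    idx_all <- idx_all[keep]
  }
  attr(out, "peak_index") <- idx_all
  out
}

# interior local maxima of a vector with plateau-first convention
plateau_maxima <- function(g) {
  r <- rle(g)
  v <- r$values
  if (length(v) < 3L) return(integer())
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  is_max <- c(FALSE, v[2:(length(v) - 1)] > v[1:(length(v) - 2)] &
                v[2:(length(v) - 1)] > v[3:length(v)], FALSE)
  starts[is_max]
}

#' Topographical atomize-and-agglomerate hierarchical clustering
#'
#' Starts with every map as its own cluster and repeatedly dissolves the
#' cluster with the lowest Correlation Sum (the sum over members of the
#' absolute spatial correlation with the cluster template), reassigning its
#' members to the remaining cluster with the highest absolute correlation.
#' Templates are the first principal axis of the member maps.  The total
#' Correlation Sum is recorded at every cluster count from `k_max` down to
#' `k_min`.
#'
#' @param maps matrix `n_maps x n_channels` (e.g. from [gfp_peaks()]).
#' @param k_min smallest cluster count retained (preset minimum 2).
#' @param k_max largest cluster count at which fits are recorded.
#' @return object of class `microstate_fit`: `correlation_sum_by_k` (named
#'   numeric, k_max..k_min), `templates_by_k` (list of k x channels unit-norm
#'   template matrices), `n_maps`, `n_channels`.
#' @export
taahc <- function(maps, k_min = 2L, k_max = 10L) {
  maps <- as.matrix(maps)
  n <- nrow(maps); p <- ncol(maps)
  if (k_max > n) stop("k_max (", k_max, ") exceeds number of maps (", n, ")")
  if (k_min < 2L) stop("k_min must be >= 2")
  nm <- normalize_maps(maps)
  if (any(nm$bad)) {
    maps <- maps[!nm$bad, , drop = FALSE]
    n <- nrow(maps)
    nm <- normalize_maps(maps)
  }
  M <- nm$maps                       # unit-norm centered maps
  cl <- seq_len(n)                   # cluster id per map
  templates <- lapply(seq_len(n), function(i) M[i, ])
  csum <- rep(1, n)                  # per-cluster correlation sum
  active <- rep(TRUE, n)
  cs_by_k <- numeric(0)
  tpl_by_k <- list()
  n_active <- n

  cluster_template <- function(members) {
    mm <- M[members, , drop = FALSE]
    if (length(members) == 1L) return(mm[1, ])
    ev <- eigen(crossprod(mm), symmetric = TRUE)$vectors[, 1]
    ev / sqrt(sum(ev^2))
  }
  refresh <- function(id) {
    members <- which(cl == id & active_map)
    tpl <- cluster_template(members)
    templates[[id]] <<- tpl
    csum[id] <<- sum(abs(M[members, , drop = FALSE] %*% tpl))
  }
  active_map <- rep(TRUE, n)         # map-level: all maps stay

  while (n_active >= k_min) {
    if (n_active <= k_max) {
      key <- as.character(n_active)
      cs_by_k[key] <- sum(csum[active])
      ids <- which(active)
      tpl_by_k[[key]] <- do.call(rbind, templates[ids])
    }
    if (n_active == k_min) break
    worst <- which(active)[which.min(csum[active])]
    members <- which(cl == worst)
    active[worst] <- FALSE
    n_active <- n_active - 1L
    rest <- which(active)
    Trest <- do.call(rbind, templates[rest])        # k x p
    corr <- abs(M[members, , drop = FALSE] %*% t(Trest))
    dest <- rest[max.col(corr, ties.method = "first")]
    cl[members] <- dest
    for (id in unique(dest)) refresh(id)
  }
  structure(list(correlation_sum_by_k = cs_by_k,
                 templates_by_k = tpl_by_k,
                 n_maps = n, n_channels = p,
                 k_range = c(k_min, min(k_max, n))),
            class = "microstate_fit")
}

#' Krzanowski-Lai choice of the number of microstates
#'
#' Converts the Correlation Sum curve to a dispersion
#' `D_k = n_maps - CorrelationSum_k`, forms
#' `DIFF(k) = (k-1)^(2/p) D_{k-1} - k^(2/p) D_k` with `p` the channel
#' count, and returns the interior `k` maximizing `|DIFF(k)/DIFF(k+1)|` —
#' the point past which the fit curve plateaus.
#'
#' @param correlation_sum_by_k named numeric vector (names = k) or a
#'   `microstate_fit`.
#' @param n_channels map dimensionality `p` (taken from the fit if given).
#' @param n_maps number of clustered maps (taken from the fit if given).
#' @return chosen `k*` (integer) with attribute `kl_index` (the ratio
#'   curve).  A flat curve (no elbow) warns and returns the earliest
#'   maximum.
#' @export
select_k_krzanowski_lai <- function(correlation_sum_by_k, n_channels = NULL,
                                    n_maps = NULL) {
  if (inherits(correlation_sum_by_k, "microstate_fit")) {
    fit <- correlation_sum_by_k
    n_channels <- fit$n_channels; n_maps <- fit$n_maps
    correlation_sum_by_k <- fit$correlation_sum_by_k
  }
  ks <- as.integer(names(correlation_sum_by_k))
  ord <- order(ks)
  ks <- ks[ord]; cs <- as.numeric(correlation_sum_by_k)[ord]
  if (length(ks) < 4L) stop("need the fit curve over at least 4 consecutive k")
  if (is.null(n_maps)) n_maps <- max(cs)
  D <- n_maps - cs
  ex <- 2 / n_channels
  diff_k <- function(i) (ks[i - 1])^ex * D[i - 1] - (ks[i])^ex * D[i]
  interior <- 2:(length(ks) - 1)          # k with both DIFF(k) and DIFF(k+1)
  kl <- vapply(interior, function(i) {
    d1 <- diff_k(i); d2 <- diff_k(i + 1)
    if (abs(d2) < .Machine$double.eps) Inf else abs(d1 / d2)
  }, 0)
  names(kl) <- ks[interior]
  fin <- kl[is.finite(kl)]
  if (length(fin) > 1 && (max(fin) - min(fin)) / max(max(fin), 1e-12) < 0.15)
    warning("Krzanowski-Lai index is nearly flat (no clear elbow); ",
            "returning the earliest maximum")
  k_star <- ks[interior][which.max(kl)]
  attr(k_star, "kl_index") <- kl
  k_star
}

#' Fit a microstate model to resting-state data
#'
#' Convenience wrapper: alpha band-pass, GFP-peak maps, TAAHC, and
#' Krzanowski-Lai selection.
#'
#' @param eeg an [epoched_eeg] of resting data.
#' @param band band-pass applied before peak extraction (default alpha).
#' @param k_min,k_max candidate cluster-count range.
#' @param max_maps cap on clustered maps (cost control).
#' @return object of class `microstate_model`: `templates` (k* x channels),
#'   `k`, `correlation_sum_by_k`, `kl_index`.
#' @export
fit_microstates <- function(eeg, band = c(8, 12), k_min = 2L, k_max = 10L,
                            max_maps = 1000L) {
  stopifnot(inherits(eeg, "epoched_eeg"))
  d <- dim(eeg$data)
  filt <- array(0, d)
  for (e in seq_len(d[1]))
    filt[e, , ] <- bandpass_filter(eeg$data[e, , ], band, eeg$fs)
  feeg <- epoched_eeg(filt, eeg$fs, eeg$channel_names,
                      pulse_sample = eeg$pulse_sample)
  maps <- gfp_peaks(feeg, max_maps = max_maps)
  fit <- taahc(maps, k_min = k_min, k_max = k_max)
  k_star <- select_k_krzanowski_lai(fit)
  structure(list(templates = fit$templates_by_k[[as.character(k_star)]],
                 k = as.integer(k_star),
                 correlation_sum_by_k = fit$correlation_sum_by_k,
                 kl_index = attr(k_star, "kl_index"),
                 band = band),
            class = "microstate_model")
}

#' Backfit microstate templates to EEG
#'
#' Labels every sample with the template of highest absolute spatial
#' correlation and computes the global explained variance
#' `GEV = sum_t (GFP_t corr_t)^2 / sum_t GFP_t^2`.  Zero-variance samples
#' take label 1 by convention and are excluded from the GEV.
#'
#' @param eeg an [epoched_eeg] or channels x samples matrix.
#' @param templates k x channels matrix (or a `microstate_model`).
#' @return object of class `label_sequence`: `labels` (`[epoch x sample]`
#'   matrix or vector, values 1..k), `gev`, `k`, `fs`.
#' @export
backfit <- function(eeg, templates) {
  if (inherits(templates, "microstate_model")) templates <- templates$templates
  templates <- as.matrix(templates)
  if (!nrow(templates)) stop("no templates")
  tn <- normalize_maps(templates)$maps
  fit_one <- function(m) {
    gfp <- global_field_power(m)
    nm <- normalize_maps(t(m))
    corr <- abs(nm$maps %*% t(tn))          # samples x k
    corr[nm$bad, ] <- 0
    lab <- max.col(corr, ties.method = "first")
    lab[nm$bad] <- 1L
    cbest <- corr[cbind(seq_along(lab), lab)]
    ok <- !nm$bad
    gev <- sum((gfp[ok] * cbest[ok])^2) / sum(gfp[ok]^2)
    list(lab = lab, gev = gev)
  }
  if (inherits(eeg, "epoched_eeg")) {
    d <- dim(eeg$data)
    labs <- matrix(0L, d[1], d[3])
    gevs <- numeric(d[1])
    for (e in seq_len(d[1])) {
      r <- fit_one(eeg$data[e, , ])
      labs[e, ] <- r$lab; gevs[e] <- r$gev
    }
    fs <- eeg$fs; gev <- mean(gevs)
    pulse <- eeg$pulse_sample
  } else {
    r <- fit_one(as.matrix(eeg))
    labs <- r$lab; gev <- r$gev; fs <- NA_real_; pulse <- NA_integer_
  }
  structure(list(labels = labs, gev = gev, k = nrow(templates), fs = fs,
                 pulse_sample = pulse),
            class = "label_sequence")
}

#' Microstate transition probability matrix
#'
#' Counts label changes (self-transitions excluded) and normalizes each row
#' to sum to one.  Rows without any exits are all zero and flagged.
#'
#' @param labels integer vector, a `label_sequence`, or a matrix whose rows
#'   are epochs (transitions are not counted across epoch boundaries).
#' @param k number of states (default: max observed / template count).
#' @return k x k row-stochastic matrix with attribute `degenerate_rows`.
#' @export
transition_probabilities <- function(labels, k = NULL) {
  if (inherits(labels, "label_sequence")) {
    if (is.null(k)) k <- labels$k
    labels <- labels$labels
  }
  rows <- if (is.matrix(labels)) lapply(seq_len(nrow(labels)),
                                        function(i) labels[i, ])
          else list(as.integer(labels))
  if (any(vapply(rows, length, 0L) < 2L)) stop("need at least 2 samples")
  if (is.null(k)) k <- max(unlist(rows))
  counts <- matrix(0, k, k)
  for (s in rows) {
    from <- s[-length(s)]; to <- s[-1]
    ch <- from != to
    if (any(ch))
      for (i in which(ch)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  ex <- rowSums(counts)
  P <- counts
  nz <- ex > 0
  P[nz, ] <- P[nz, , drop = FALSE] / ex[nz]
  attr(P, "degenerate_rows") <- which(!nz)
  if (!any(nz)) warning("label sequence is constant: all rows degenerate")
  P
}
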