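# Synthetic EEG cohorts and connectomes.  The generator plants exactly the
# structure the analysis pipeline assumes: metastable switching of
# synchrony among a small set of narrowband Kuramoto sources, an
# alpha-dominant spectrum, a handful of quasi-stable sensor topographies
# (microstate-like), and -- for TMS runs -- a phase reset of a local source
# cluster with a superimposed biphasic evoked deflection.

#' Synthetic cohort specification
#'
#' Defaults mirror the shape of a 32-channel single-pulse TMS-EEG study:
#' 20 subjects, 60 epochs of 2 s at 1 kHz with the pulse at 500 ms.
#'
#' @param n_subjects,n_epochs,n_channels,fs,epoch_ms,pulse_ms cohort shape.
#' @param n_sources number of cortical sources (>= 2).
#' @param source_band frequency band the sources oscillate in, Hz.
#' @param n_states number of planted quasi-stable topography states
#'   (microstate analog); 0 disables state switching.
#' @param state_dwell_ms mean dwell time of a state.
#' @param reset_strength fraction of cluster sources phase-reset at the
#'   pulse, in [0, 1].
#' @param recovery_tau_ms decay time constant of the post-reset coherence
#'   hold.
#' @param evoked_amplitude peak of the biphasic evoked deflection, uV.
#' @param anticipation_effect if `TRUE`, source phase jitter ramps up
#'   linearly over the 250 ms before the pulse.
#' @param noise_uv sensor white-noise standard deviation, uV.
#' @param signal_rms_uv target RMS of the mixed source signal, uV.
#' @param source_coupling,source_noise Kuramoto working point of the source
#'   network (coupling in rad/ms; noise as the dimensionless scale d).
#' @param seed integer RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, n_epochs = 60, n_channels = 32,
                        fs = 1000, epoch_ms = 2000, pulse_ms = 500,
                        n_sources = 8, source_band = c(8, 12),
                        n_states = 4, state_dwell_ms = 100,
                        reset_strength = 1, recovery_tau_ms = 100,
                        evoked_amplitude = 15, anticipation_effect = FALSE,
                        noise_uv = 2, signal_rms_uv = 10,
                        source_coupling = 0.015, source_noise = 3,
                        seed = 1L) {
  stopifnot(n_sources >= 2, reset_strength >= 0, reset_strength <= 1,
            pulse_ms > 0, pulse_ms < epoch_ms, fs > 0,
            n_states <= n_sources)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Synthetic connectome specification
#'
#' @param n_nodes node count (default 90, an AAL-sized parcellation).
#' @param sphere_radius_mm node coordinates are drawn uniformly in a
#'   sphere of this radius.
#' @param decay_length_mm weights decay as `exp(-d / lambda)`.
#' @param conduction_velocity_m_s scales distances into delays.
#' @param seed integer RNG seed.
#' @return list of class `connectome_spec`.
#' @export
connectome_spec <- function(n_nodes = 90, sphere_radius_mm = 70,
                            decay_length_mm = 30,
                            conduction_velocity_m_s = 7, seed = 1L) {
  stopifnot(n_nodes >= 2, conduction_velocity_m_s > 0)
  structure(as.list(environment()), class = "connectome_spec")
}

#' Generate a synthetic connectome
#'
#' Seeded node coordinates uniform in a sphere; symmetric nonnegative
#' weights `w_ij = exp(-d_ij / lambda)` with zero diagonal; Euclidean
#' distances in mm; conduction delays `tau_ij = d_ij / velocity`.
#'
#' @param spec a [connectome_spec()].
#' @return a [connectome].
#' @export
generate_connectome <- function(spec = connectome_spec()) {
  stopifnot(inherits(spec, "connectome_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  # uniform in a ball by rejection-free radius transform
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  coords <- u * spec$sphere_radius_mm * runif(n)^(1 / 3)
  d <- as.matrix(stats::dist(coords))
  w <- exp(-d / spec$decay_length_mm)
  diag(w) <- 0
  connectome(w, d, velocity_m_s = spec$conduction_velocity_m_s,
             coordinates = coords)
}

# biphasic evoked kernel: difference of two Gaussians, peak ~30 ms
evoked_kernel <- function(t_ms) {
  k <- exp(-(t_ms - 30)^2 / (2 * 10^2)) - 0.7 * exp(-(t_ms - 65)^2 / (2 * 18^2))
  k[t_ms < 0] <- 0
  k / max(k)
}

# dipolar topography of a source at `p`: positive Gaussian at the source,
# negative pole tangentially offset, so each source projects to a local
# channel neighborhood with both polarities (localized mixing)
source_topography <- function(positions, p, sigma_mm = 25, offset_mm = 45) {
  tang <- c(-p[2], p[1], 0)
  nt <- sqrt(sum(tang^2))
  if (nt < 1e-6) tang <- c(1, 0, 0) else tang <- tang / nt
  q <- p + offset_mm * tang
  dp <- sqrt(rowSums((positions - matrix(p, nrow(positions), 3, byrow = TRUE))^2))
  dq <- sqrt(rowSums((positions - matrix(q, nrow(positions), 3, byrow = TRUE))^2))
  v <- exp(-dp^2 / (2 * sigma_mm^2)) - exp(-dq^2 / (2 * sigma_mm^2))
  v / sqrt(sum(v^2))
}

# sensors on an upper spherical cap of radius 90 mm
sensor_positions <- function(n_ch, radius = 90) {
  gold <- pi * (3 - sqrt(5))
  i <- seq_len(n_ch) - 1
  z <- 1 - i / n_ch * 0.9            # cap: z in (0.1, 1]
  th <- gold * i
  r2 <- sqrt(1 - z^2)
  cbind(x = radius * r2 * cos(th), y = radius * r2 * sin(th), z = radius * z)
}

# Markov state sequence with geometric dwell
state_sequence <- function(n_samples, n_states, dwell_samples) {
  s <- integer(n_samples)
  cur <- sample.int(n_states, 1L)
  p_switch <- 1 / dwell_samples
  flips <- runif(n_samples) < p_switch
  for (t in seq_len(n_samples)) {
    if (flips[t]) {
      nxt <- sample.int(n_states - 1L, 1L)
      cur <- if (nxt >= cur) nxt + 1L else nxt
    }
    s[t] <- cur
  }
  s
}

run_sources <- function(spec, n_samples, reset = FALSE, burn_ms = 500) {
  ns <- spec$n_sources
  dt <- 0.5
  store_every <- as.integer(round(1000 / spec$fs / dt))
  stopifnot(store_every >= 1)
  burn <- round(burn_ms * spec$fs / 1000)   # stationarize before the epoch
  n_keep <- n_samples
  n_samples <- n_samples + burn
  n_steps <- n_samples * store_every
  C <- matrix(1, ns, ns); diag(C) <- 0
  tau <- matrix(0L, ns, ns)
  f <- runif(ns, spec$source_band[1], spec$source_band[2])
  omega <- 2 * pi * f / 1000
  theta0 <- runif(ns, -pi, pi)
  d_eff <- spec$source_noise / sqrt(1000)   # d is per sqrt(second)
  n_cluster <- max(2L, round(ns / 3))
  cluster <- seq_len(n_cluster)
  reset_step <- rep(-1L, ns)
  k_extra <- numeric(0); extra_idx <- integer(0)
  d_t <- d_eff
  if (reset) {
    pulse_step <- as.integer(round((spec$pulse_ms + burn_ms) / dt))
    n_reset <- round(spec$reset_strength * n_cluster)
    if (n_reset > 0) reset_step[cluster[seq_len(n_reset)]] <- pulse_step
    # decaying coherence hold among the cluster, time constant recovery_tau
    pulse_t <- spec$pulse_ms + burn_ms
    if (spec$reset_strength > 0) {
      tgrid <- (seq_len(n_steps) - 1) * dt
      k_extra <- ifelse(tgrid >= pulse_t,
                        0.5 * spec$reset_strength *
                          exp(-(tgrid - pulse_t) / spec$recovery_tau_ms),
                        0)
      extra_idx <- cluster - 1L             # 0-based for C++
    }
    if (spec$anticipation_effect) {
      tgrid <- (seq_len(n_steps) - 1) * dt
      ramp <- pmax(0, 1 - (pulse_t - tgrid) / 250)
      ramp[tgrid > pulse_t] <- 0
      d_t <- d_eff * (1 + ramp)
    }
  }
  res <- twin_integrate_cpp(C, tau, omega, spec$source_coupling,
                            d_t, dt, n_steps, theta0, reset_step, pi / 2,
                            extra_idx, k_extra, store_every)
  theta <- res$theta[, burn + seq_len(n_keep), drop = FALSE]
  list(theta = theta, f = f, cluster = cluster)
}

generate_cohort <- function(spec, tms) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_samp <- round(spec$epoch_ms * spec$fs / 1000)
  pulse_sample <- round(spec$pulse_ms * spec$fs / 1000) + 1L
  pos <- sensor_positions(spec$n_channels)
  t_ms <- (seq_len(n_samp) - 1) / spec$fs * 1000
  dwell <- spec$state_dwell_ms * spec$fs / 1000
  subjects <- vector("list", spec$n_subjects)
  planted <- vector("list", spec$n_subjects)
  for (subj in seq_len(spec$n_subjects)) {
    # source locations on the head sphere; sources sorted by distance to the
    # first (the "stimulation site") so the local cluster is sources 1..m
    src_pos <- sensor_positions(spec$n_sources, radius = 80)
    src_pos <- src_pos[sample(spec$n_sources), , drop = FALSE]
    ord <- order(sqrt(rowSums((src_pos -
      matrix(src_pos[1, ], spec$n_sources, 3, byrow = TRUE))^2)))
    src_pos <- src_pos[ord, , drop = FALSE]
    M <- vapply(seq_len(spec$n_sources),
                function(s) source_topography(pos, src_pos[s, ]),
                numeric(spec$n_channels))
    n_cluster <- max(2L, round(spec$n_sources / 3))
    evoked_topo <- rowSums(M[, seq_len(n_cluster), drop = FALSE])
    evoked_topo <- evoked_topo / max(abs(evoked_topo))
    # transient post-pulse dominance of the coherent cluster, decaying with
    # the same time constant as the coherence hold
    boost <- if (tms && spec$reset_strength > 0)
      1 + 2 * spec$reset_strength *
        exp(-pmax(t_ms - spec$pulse_ms, 0) / spec$recovery_tau_ms) *
        (t_ms >= spec$pulse_ms)
    else rep(1, n_samp)
    arr <- array(0, c(spec$n_epochs, spec$n_channels, n_samp))
    for (ep in seq_len(spec$n_epochs)) {
      src <- run_sources(spec, n_samp, reset = tms)
      gains <- matrix(1, spec$n_sources, n_samp)
      if (spec$n_states > 0) {
        st <- state_sequence(n_samp, spec$n_states, dwell)
        for (k in seq_len(spec$n_states)) {
          gains[k, ] <- ifelse(st == k, 3, 0.5)
        }
      }
      gains[seq_len(n_cluster), ] <-
        gains[seq_len(n_cluster), , drop = FALSE] *
        matrix(boost, n_cluster, n_samp, byrow = TRUE)
      sig <- M %*% (gains * cos(src$theta))
      rms <- if (tms) sqrt(mean(sig[, t_ms < spec$pulse_ms]^2))
             else sqrt(mean(sig^2))
      if (rms > 0) sig <- sig * spec$signal_rms_uv / rms
      sig <- sig + matrix(rnorm(length(sig), sd = spec$noise_uv),
                          nrow(sig), ncol(sig))
      if (tms && spec$evoked_amplitude > 0 && spec$reset_strength > 0) {
        # TEP amplitude scales with the reset fraction: one intensity knob,
        # so reset_strength = 0 is a clean null (identical to resting)
        shape <- evoked_kernel(t_ms - spec$pulse_ms)
        sig <- sig + spec$reset_strength * spec$evoked_amplitude *
          outer(evoked_topo, shape)
      }
      arr[ep, , ] <- sig
    }
    subjects[[subj]] <- epoched_eeg(
      arr, fs = spec$fs,
      pulse_sample = if (tms) pulse_sample else NA_integer_,
      channel_positions = pos,
      subject_id = sprintf("sub-%02d", subj))
    # planted channel groups: one tertile per dipole pole (mixed-polarity
    # sets would cancel in the order parameter)
    g <- floor(spec$n_channels / 3)
    ord_t <- order(evoked_topo)
    planted[[subj]] <- list(mixing = M, evoked_topo = evoked_topo,
                            source_positions = src_pos,
                            cluster_sources = seq_len(n_cluster),
                            cluster_channels = sort(ord_t[
                              (spec$n_channels - g + 1):spec$n_channels]),
                            cluster_channels_neg = sort(ord_t[seq_len(g)]))
  }
  structure(list(subjects = subjects, spec = spec, planted = planted,
                 kind = if (tms) "tms" else "resting"),
            class = "synthetic_cohort")
}

#' Generate a resting-state synthetic cohort (no pulse)
#'
#' Sources are phases of a small Kuramoto network at a metastable working
#' point, narrowband in `source_band`; sensors are a smooth dipolar random
#' mixing of the source cosines plus white noise, with `n_states` planted
#' alternately-dominant topographies.
#'
#' @param spec a [cohort_spec()].
#' @return `synthetic_cohort`: `subjects` (list of [epoched_eeg]), `spec`,
#'   `planted` (per-subject mixing and cluster metadata).
#' @export
generate_resting_eeg <- function(spec = cohort_spec()) {
  generate_cohort(spec, tms = FALSE)
}

#' Generate a TMS-EEG synthetic cohort
#'
#' Identical generative model to [generate_resting_eeg()], plus the planted
#' pulse effect: at `pulse_ms` a fraction `reset_strength` of the sources
#' in a designated local cluster is phase-reset to a common value; cluster
#' coherence then decays back with time constant `recovery_tau_ms`; a
#' biphasic evoked deflection of `evoked_amplitude` uV (peak 30 ms
#' post-pulse) is added with the cluster's dipolar topography.  With
#' `anticipation_effect`, source jitter ramps up over the 250 ms before
#' the pulse.
#'
#' @param spec a [cohort_spec()].
#' @return `synthetic_cohort` (see [generate_resting_eeg()]).
#' @export
generate_tms_epochs <- function(spec = cohort_spec()) {
  generate_cohort(spec, tms = TRUE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %s: %d subjects x %d epochs x %d ch @ %g Hz\n",
              x$kind, length(x$subjects), x$spec$n_epochs, x$spec$n_channels,
              x$spec$fs))
  invisible(x)
}
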