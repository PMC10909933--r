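# The digital twin: a delayed Kuramoto network on a (synthetic or
# supplied) structural connectome,
#
#   dtheta_i/dt = omega_i + (K/N) sum_j c_ij sin(theta_j(t - tau_ij) - theta_i)
#                 + d zeta(t),
#
# integrated with Euler-Maruyama.  A TMS pulse is a phase reset to pi/2
# that reaches the stimulated region instantly and every other node after
# its conduction delay to the site.

#' Structural connectome
#'
#' @param weights symmetric nonnegative matrix `c_ij`, zero diagonal.
#' @param distances symmetric inter-node distances, mm.
#' @param velocity_m_s conduction velocity (m/s); delays are
#'   `tau_ij = d_ij / v` in ms.
#' @param coordinates optional n x 3 node coordinates, mm.
#' @param node_labels optional names (e.g. AAL region labels).
#' @return object of class `connectome` with `weights`, `distances`,
#'   `delays_ms`, `strengths` (row sums of weights), `velocity_m_s`.
#' @export
connectome <- function(weights, distances, velocity_m_s = 7,
                       coordinates = NULL, node_labels = NULL) {
  weights <- as.matrix(weights); distances <- as.matrix(distances)
  n <- nrow(weights)
  stopifnot(ncol(weights) == n, all(dim(distances) == n), velocity_m_s > 0)
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (max(abs(weights - t(weights))) > 1e-8) stop("weights must be symmetric")
  diag(weights) <- 0
  delays <- distances / velocity_m_s     # mm / (m/s) = ms
  diag(delays) <- 0
  if (is.null(node_labels)) node_labels <- sprintf("node%02d", seq_len(n))
  structure(list(weights = weights, distances = distances,
                 delays_ms = delays, strengths = unname(rowSums(weights)),
                 coordinates = coordinates, node_labels = node_labels,
                 velocity_m_s = velocity_m_s, n_nodes = n),
            class = "connectome")
}

#' Intrinsic frequencies from node strength
#'
#' Hubs oscillate slowest: `f_i = f_max - f_spread (s_i - s_min) /
#' (s_max - s_min)`, so the strongest node sits at `f_max - f_spread` and
#' the weakest at `f_max`.  Shifting `f_max` translates every frequency,
#' keeping the dispersion fixed.
#'
#' @param strengths nonnegative node strengths, not all equal.
#' @param f_max maximum frequency, Hz (the sweep uses 5, 15, 25, 35).
#' @param f_spread dispersion of the distribution, Hz (default 3).
#' @return list with `f_hz` and `omega` (rad/ms).
#' @export
assign_frequencies <- function(strengths, f_max = 15, f_spread = 3) {
  rng <- range(strengths)
  if (diff(rng) < .Machine$double.eps) stop("all node strengths equal")
  f <- f_max - f_spread * (strengths - rng[1]) / diff(rng)
  list(f_hz = f, omega = 2 * pi * f / 1000)
}

#' Twin simulation parameters
#'
#' @param K global coupling scale (default 0.15: the argmax of the
#'   metastability grid search on the default synthetic connectome at
#'   7 m/s; see [tune_working_point()]).
#' @param noise_d noise scale `d` (default 3; unit-sd Gaussian increments
#'   scaled by this factor).
#' @param noise_model how `d zeta(t)` is discretized.  `"diffusion"`
#'   (default) is Euler-Maruyama, `sqrt(dt) * d * zeta` with `d` in
#'   rad/sqrt(s): stochastic switching dominates and post-reset coherence
#'   decays within hundreds of ms.  `"drift"` is the literal Euler reading
#'   (noise inside the derivative, `dt * d * zeta`, `d` in rad/s):
#'   numerically near-deterministic, with seconds-long locked states.  The
#'   methods vignette discusses the trade-off.
#' @param dt Euler step, ms (default 0.1; must not exceed the smallest
#'   positive delay).
#' @param duration_ms simulated time.
#' @param f_max,f_spread frequency distribution (see
#'   [assign_frequencies()]).
#' @param seed RNG seed used by [simulate_twin()].
#' @param store_every store every so-many steps (thins the output).
#' @return list of class `twin_params`.
#' @export
twin_params <- function(K = 0.15, noise_d = 3, dt = 0.1, duration_ms = 5000,
                        f_max = 15, f_spread = 3, seed = 1L,
                        store_every = 10L,
                        noise_model = c("diffusion", "drift")) {
  stopifnot(dt > 0, K >= 0, duration_ms > 0, store_every >= 1)
  noise_model <- match.arg(noise_model)
  structure(list(K = K, noise_d = noise_d, dt = dt,
                 duration_ms = duration_ms, f_max = f_max,
                 f_spread = f_spread, seed = as.integer(seed),
                 store_every = as.integer(store_every),
                 noise_model = noise_model),
            class = "twin_params")
}

#' Simulate the delayed Kuramoto network
#'
#' Euler-Maruyama integration (`theta += dt (omega + coupling) +
#' sqrt(dt) d zeta`).  Delays are rounded to integer steps; history before
#' t = 0 is backfilled by backward extrapolation at the intrinsic
#' frequencies from the random initial phases.  With `reset` given, the
#' phase of each node is forced to `reset$value` at `reset$time_ms` plus
#' that node's conduction delay to the stimulation site (instant inside
#' `reset$instant_radius_mm`).  Because the noise stream depends only on
#' the seed, the trajectory with a reset is identical to the unperturbed
#' one up to the pulse.
#'
#' @param conn a [connectome].
#' @param params a [twin_params].
#' @param theta0 optional initial phases (default uniform on the circle,
#'   drawn under the seed).
#' @param reset optional list: `time_ms`, `site` (node index),
#'   `instant_radius_mm` (default 20), `value` (default pi/2).
#' @param omega optional explicit intrinsic frequencies (rad/ms),
#'   bypassing the strength-based assignment.
#' @return object of class `twin_run`: `theta` (n x time, wrapped),
#'   `time_ms`, `fs` (stored sampling rate, Hz), `omega`, `params`,
#'   `reset_schedule_ms` (per-node reset times or NULL).
#' @export
simulate_twin <- function(conn, params, theta0 = NULL, reset = NULL,
                          omega = NULL) {
  stopifnot(inherits(conn, "connectome"), inherits(params, "twin_params"))
  n <- conn$n_nodes
  dt <- params$dt
  pos_delays <- conn$delays_ms[conn$delays_ms > 0]
  if (length(pos_delays) && dt > min(pos_delays))
    stop("dt (", dt, " ms) exceeds the smallest positive delay (",
         signif(min(pos_delays), 3), " ms)")
  tau_steps <- matrix(as.integer(round(conn$delays_ms / dt)), n, n)
  if (is.null(omega))
    omega <- assign_frequencies(conn$strengths, params$f_max,
                                params$f_spread)$omega
  n_steps <- as.integer(round(params$duration_ms / dt))
  set.seed(params$seed)
  if (is.null(theta0)) theta0 <- runif(n, -pi, pi)
  reset_step <- rep(-1L, n)
  sched <- NULL
  if (!is.null(reset)) {
    site <- reset$site
    stopifnot(site >= 1, site <= n)
    radius <- reset$instant_radius_mm %||% 20
    value <- reset$value %||% (pi / 2)
    inst <- which(conn$distances[, site] <= radius)
    inst <- union(inst, site)
    sched <- reset$time_ms + conn$delays_ms[, site]
    sched[inst] <- reset$time_ms
    reset_step <- as.integer(round(sched / dt))
    if (any(reset_step < 1L | reset_step > n_steps))
      stop("reset schedule outside the simulated interval")
    attr(sched, "instant_nodes") <- inst
    attr(sched, "value") <- value
  }
  # the integrator multiplies the noise vector by sqrt(dt); rescale so that
  # "drift" mode yields dt * (d rad/s) * zeta and "diffusion" mode yields
  # sqrt(dt) * (d rad/sqrt(s)) * zeta, with dt in ms
  d_eff <- if (identical(params$noise_model %||% "diffusion", "diffusion"))
    params$noise_d / sqrt(1000)
  else
    sqrt(dt) * params$noise_d / 1000
  res <- twin_integrate_cpp(conn$weights, tau_steps, omega, params$K,
                            d_eff, dt, n_steps, theta0,
                            reset_step,
                            if (is.null(reset)) 0 else (reset$value %||% (pi / 2)),
                            integer(), numeric(), params$store_every)
  dt_store <- dt * params$store_every
  nt <- ncol(res$theta)
  structure(list(theta = res$theta, time_ms = (seq_len(nt) - 1) * dt_store,
                 fs = 1000 / dt_store, omega = omega, params = params,
                 conn = conn, reset_schedule_ms = sched,
                 pulse_time_ms = if (is.null(reset)) NA_real_ else reset$time_ms),
            class = "twin_run")
}

#' Network or subgroup KOP of a twin run
#'
#' @param run a `twin_run`.
#' @param nodes node subset (default all).
#' @return `kop_trace` (single "epoch") with `r`, `psi`, `time_ms`.
#' @export
twin_kop <- function(run, nodes = NULL) {
  th <- if (is.null(nodes)) run$theta else run$theta[nodes, , drop = FALSE]
  z <- colMeans(exp(1i * th))
  structure(list(r = Mod(z), psi = Arg(z), fs = run$fs,
                 time_ms = run$time_ms, band = NULL,
                 channel_set = if (is.null(nodes)) run$conn$node_labels
                               else run$conn$node_labels[nodes],
                 pulse_sample = if (is.na(run$pulse_time_ms)) NA_integer_
                   else which.min(abs(run$time_ms - run$pulse_time_ms)),
                 valid = c(1L, length(z))),
            class = "kop_trace")
}

#' Apply a propagating TMS phase reset
#'
#' Re-simulates the run's realization (same seed, hence identical noise and
#' identical trajectory before the pulse) with the phase of the stimulated
#' region forced to `reset_value` at `pulse_time_ms` and every remaining
#' node reset after its conduction delay to the site.
#'
#' @param conn [connectome]; @param params [twin_params].
#' @param pulse_time_ms pulse time (choose with
#'   [find_low_coherence_times()]).
#' @param site stimulated node index.
#' @param instant_radius_mm nodes within this Euclidean distance of the
#'   site reset instantly (geometric stand-in for the stimulated field).
#' @param reset_value forced phase (default pi/2).
#' @param extend_ms extra simulated time appended after the original
#'   duration (default 0).
#' @return `twin_run` with `reset_schedule_ms` filled.
#' @export
apply_tms_reset <- function(conn, params, pulse_time_ms, site,
                            instant_radius_mm = 20, reset_value = pi / 2,
                            extend_ms = 0) {
  params$duration_ms <- params$duration_ms + extend_ms
  simulate_twin(conn, params,
                reset = list(time_ms = pulse_time_ms, site = site,
                             instant_radius_mm = instant_radius_mm,
                             value = reset_value))
}

#' Candidate pulse times at low-coherence states
#'
#' Local minima of the 25 ms moving-averaged KOP trace after a burn-in,
#' keeping minima whose prominence is at least half the standard deviation
#' of the (smoothed, post-burn-in) trace.
#'
#' @param kop_trace a `kop_trace` (from [twin_kop()]).
#' @param burn_in_ms discard this initial transient (default 2000 ms).
#' @param smooth_ms moving-average window (default 25 ms).
#' @return numeric vector of candidate times (ms), sorted.
#' @export
find_low_coherence_times <- function(kop_trace, burn_in_ms = 2000,
                                     smooth_ms = 25) {
  r <- kop_trace$r; tm <- kop_trace$time_ms
  if (max(tm) <= burn_in_ms) stop("trace shorter than burn-in")
  w <- max(1L, round(smooth_ms * kop_trace$fs / 1000))
  if (w > length(r)) stop("smoothing window longer than trace")
  sm <- moving_average(r, w)
  keep <- which(tm > burn_in_ms & !is.na(sm))
  seg <- sm[keep]
  if (sd(seg) < 1e-10) stop("KOP trace is constant: no low-coherence states")
  mins <- local_minima(seg, min_prom = 0.5 * sd(seg))
  if (!length(mins)) stop("no qualifying coherence minima; run the ",
                          "simulation longer or lower the burn-in")
  sort(tm[keep][mins])
}

#' Oscillators with intrinsic frequency near a target node's
#'
#' @param omega rad/ms frequencies (or `f_hz` vector).
#' @param target_node index whose frequency anchors the subgroup.
#' @param tolerance_hz half-width of the frequency window.
#' @return integer node indices (always includes the target).
#' @export
select_subgroup <- function(omega, target_node, tolerance_hz = 1) {
  f <- if (max(abs(omega)) < 1) omega * 1000 / (2 * pi) else omega
  sel <- which(abs(f - f[target_node]) <= tolerance_hz)
  sort(union(sel, target_node))
}

#' Grid search for a metastable working point
#'
#' Runs a short simulation per (K, velocity) cell and scores each by the
#' time-averaged sliding-window standard deviation of the network KOP.
#' Returns the argmax cell and the full score table.
#'
#' @param conn [connectome] (its velocity is overridden per cell).
#' @param K_grid,velocity_grid candidate values.
#' @param params base [twin_params] (short `duration_ms` recommended).
#' @param window_ms metastability window for scoring (default 500).
#' @param burn_in_ms scored portion starts here.
#' @return list `K`, `velocity_m_s`, `table` (data.frame K, velocity,
#'   score).
#' @export
tune_working_point <- function(conn, K_grid, velocity_grid, params,
                               window_ms = 500, burn_in_ms = 1000) {
  stopifnot(length(K_grid) >= 1, length(velocity_grid) >= 1)
  rows <- list()
  for (v in velocity_grid) {
    cv <- connectome(conn$weights, conn$distances, velocity_m_s = v,
                     coordinates = conn$coordinates,
                     node_labels = conn$node_labels)
    for (K in K_grid) {
      p <- params; p$K <- K
      run <- simulate_twin(cv, p)
      kt <- twin_kop(run)
      ms <- sliding_metastability(kt, window_ms = window_ms)
      sel <- ms$time_ms > burn_in_ms & !is.na(ms$value)
      rows[[length(rows) + 1L]] <-
        data.frame(K = K, velocity_m_s = v,
                   score = mean(ms$value[sel]),
                   mean_r = mean(kt$r[kt$time_ms > burn_in_ms]))
    }
  }
  tab <- do.call(rbind, rows)
  if (max(tab$score) < 1e-6)
    warning("all grid cells show near-constant KOP; returning argmax anyway")
  best <- tab[which.max(tab$score), ]
  list(K = best$K, velocity_m_s = best$velocity_m_s, table = tab)
}

# Windowed population std of r that never straddles the reset: windows in
# the pre segment are right-aligned (value at t summarizes [t-w+1, t]),
# windows in the post segment left-aligned ([t, t+w-1]).  This mirrors the
# removal of the pulse discontinuity in the original analysis; without it
# the artificial phase jump would dominate every window crossing the pulse.
segmented_metastability <- function(r, i_pulse, w) {
  n <- length(r)
  out <- rep(NaN, n)
  seg_sd <- function(x) {
    m <- length(x)
    if (m < w) return(numeric(0))
    cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
    mu <- (cs[(w + 1):(m + 1)] - cs[1:(m - w + 1)]) / w
    mu2 <- (cs2[(w + 1):(m + 1)] - cs2[1:(m - w + 1)]) / w
    sqrt(pmax(mu2 - mu^2, 0))
  }
  if (i_pulse > 1) {
    s <- seg_sd(r[1:(i_pulse - 1)])
    if (length(s)) out[w:(i_pulse - 1)] <- s          # right-aligned
  }
  if (i_pulse <= n) {
    s <- seg_sd(r[i_pulse:n])
    if (length(s)) out[i_pulse:(i_pulse + length(s) - 1L)] <- s  # left-aligned
  }
  out
}

#' Pulse-aligned, seed-averaged twin experiment
#'
#' For each maximum frequency and seed: simulate, pick the first
#' low-coherence state after burn-in, deliver the propagating phase reset
#' there, compute the subgroup KOP and its sliding metastability, align
#' both traces to the pulse, and average across seeds.  Also reports the
#' post-pulse recovery time of metastability: the first time after the
#' pulse at which the seed-averaged trace re-enters a +/-1 SD band around
#' its pre-pulse baseline mean.
#'
#' @param conn [connectome].
#' @param base_params [twin_params]; `duration_ms` is the pre-pulse search
#'   length (pulse must occur after `burn_in_ms`).
#' @param f_max_list maximum frequencies swept (default `c(5,15,25,35)`).
#' @param n_seeds seeds per frequency (default 20).
#' @param site stimulated node (default: node of median strength).
#' @param tolerance_hz subgroup half-width (default 1 Hz).
#' @param window_ms metastability window (default 500 ms).
#' @param pre_ms,post_ms aligned trace extent around the pulse.
#' @param burn_in_ms low-coherence search starts here (default 2000).
#' @param instant_radius_mm instant-reset radius (default 20 mm).
#' @return object of class `twin_experiment`: per-f_max list with
#'   `kop_mean`, `meta_mean` (aligned averages), `time_ms` (0 = pulse),
#'   `recovery_ms`, `per_seed` (pre/post window means per seed), `n_seeds`.
#' @export
run_experiment <- function(conn, base_params, f_max_list = c(5, 15, 25, 35),
                           n_seeds = 20, site = NULL, tolerance_hz = 1,
                           window_ms = 500, pre_ms = 2000, post_ms = 2000,
                           burn_in_ms = 2000, instant_radius_mm = 20) {
  if (is.null(site)) site <- order(conn$strengths)[ceiling(conn$n_nodes / 2)]
  dt_store <- base_params$dt * base_params$store_every
  n_pre <- round(pre_ms / dt_store); n_post <- round(post_ms / dt_store)
  rel_time <- (seq_len(n_pre + n_post + 1) - n_pre - 1) * dt_store
  out <- list()
  for (fm in f_max_list) {
    kops <- NULL; metas <- NULL
    per_seed <- list()
    used <- 0L
    for (s in seq_len(n_seeds)) {
      seed_s <- base_params$seed + 7919L * s + as.integer(fm)
      p <- base_params; p$seed <- seed_s; p$f_max <- fm
      res <- tryCatch({
        search <- simulate_twin(conn, p)
        cand <- find_low_coherence_times(twin_kop(search),
                                         burn_in_ms = burn_in_ms)
        t_p <- cand[1]
        run <- apply_tms_reset(conn, p, pulse_time_ms = t_p, site = site,
                               instant_radius_mm = instant_radius_mm,
                               extend_ms = max(0, t_p + post_ms + window_ms -
                                                 p$duration_ms))
        sub <- select_subgroup(run$omega, site, tolerance_hz)
        kt <- twin_kop(run, nodes = sub)
        i_p <- which.min(abs(run$time_ms - t_p))
        w_samp <- round(window_ms * run$fs / 1000)
        msv <- segmented_metastability(kt$r, i_p + 1L, w_samp)
        idx <- (i_p - n_pre):(i_p + n_post)
        if (idx[1] < 1 || idx[length(idx)] > length(kt$r))
          stop("aligned window exceeds run")
        list(kop = kt$r[idx], meta = msv[idx],
             pre_kop = mean(kt$r[idx][rel_time >= -250 & rel_time < 0]),
             post_kop = mean(kt$r[idx][rel_time > 0 & rel_time <= 250]),
             pre_meta = mean(msv[idx][rel_time >= -250 & rel_time < 0],
                             na.rm = TRUE),
             post_meta = mean(msv[idx][rel_time > 0 & rel_time <= 250],
                              na.rm = TRUE))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        message("f_max ", fm, " seed ", s, " failed: ", conditionMessage(res))
        next
      }
      used <- used + 1L
      kops <- rbind(kops, res$kop); metas <- rbind(metas, res$meta)
      per_seed[[used]] <- data.frame(seed = seed_s, pre_kop = res$pre_kop,
                                     post_kop = res$post_kop,
                                     pre_meta = res$pre_meta,
                                     post_meta = res$post_meta)
    }
    if (!used) stop("every seed failed for f_max = ", fm)
    kop_mean <- colMeans(kops); meta_mean <- colMeans(metas, na.rm = TRUE)
    base_sel <- rel_time < 0 & is.finite(meta_mean)
    b_mu <- mean(meta_mean[base_sel], na.rm = TRUE)
    # band width: typical single-run baseline variability (stable across
    # f_max), not the sd of the n-seed average (which shrinks with n)
    b_sd <- mean(apply(metas[, base_sel, drop = FALSE], 1, stats::sd,
                       na.rm = TRUE))
    # the reset first inflates the windowed std (coherence ramp), then the
    # locked state depresses it (the dip); recovery is the return to the
    # +/-1 SD baseline band from the dip, i.e. after the post-trace minimum
    post_i <- which(rel_time > 0 & is.finite(meta_mean))
    dip_i <- post_i[which.min(meta_mean[post_i])]
    dip_ms <- rel_time[dip_i]
    dip_depth <- b_mu - meta_mean[dip_i]
    after <- post_i[post_i >= dip_i]
    inside <- abs(meta_mean[after] - b_mu) <= b_sd
    recovery_ms <- if (any(inside, na.rm = TRUE))
      rel_time[after][which(inside)[1]] else NA_real_
    out[[as.character(fm)]] <- list(
      f_max = fm, kop_mean = kop_mean, meta_mean = meta_mean,
      time_ms = rel_time, recovery_ms = recovery_ms,
      dip_ms = dip_ms, dip_depth = dip_depth,
      baseline_mean = b_mu, baseline_sd = b_sd,
      per_seed = do.call(rbind, per_seed), n_seeds = used,
      site = site)
  }
  structure(out, class = "twin_experiment")
}
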