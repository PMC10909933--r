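test_that("synthetic connectome has the advertised analytic structure", {
  spec <- connectome_spec(n_nodes = 40, seed = 9)
  conn <- generate_connectome(spec)
  expect_true(isSymmetric(conn$weights))
  expect_equal(unname(diag(conn$weights)), rep(0, 40))
  # w_ij = exp(-d_ij / lambda) off-diagonal
  off <- upper.tri(conn$weights)
  expect_equal(conn$weights[off],
               exp(-conn$distances[off] / spec$decay_length_mm))
  # two nodes at distance lambda -> weight e^-1; tau = d / v
  d2 <- matrix(c(0, 30, 30, 0), 2)
  c2 <- connectome(exp(-d2 / 30) - diag(2) * exp(0), d2, velocity_m_s = 7)
  expect_equal(c2$weights[1, 2], exp(-1), tolerance = 1e-12)
  c3 <- connectome(matrix(c(0, 1, 1, 0), 2), matrix(c(0, 70, 70, 0), 2),
                   velocity_m_s = 7)
  expect_equal(c3$delays_ms[1, 2], 10)
  # determinism
  conn2 <- generate_connectome(spec)
  expect_identical(conn$weights, conn2$weights)
  expect_error(generate_connectome(connectome_spec(n_nodes = 1)), "n_nodes")
})

test_that("assign_frequencies maps strength linearly, hubs slowest", {
  f <- assign_frequencies(c(0, 1), f_max = 15, f_spread = 3)
  expect_equal(f$f_hz, c(15, 12))
  s <- runif(20, 2, 9)
  f15 <- assign_frequencies(s, 15, 3)$f_hz
  f25 <- assign_frequencies(s, 25, 3)$f_hz
  expect_equal(f25 - f15, rep(10, 20))           # translation, spread kept
  expect_equal(max(f15), 15)
  expect_equal(min(f15), 12)
  expect_error(assign_frequencies(rep(2, 5), 15, 3), "equal")
})

test_that("decoupled noise-free integration matches the closed form", {
  conn <- generate_connectome(connectome_spec(n_nodes = 12, seed = 10))
  p <- twin_params(K = 0, noise_d = 0, dt = 0.1, duration_ms = 200,
                   seed = 3, store_every = 1)
  run <- simulate_twin(conn, p)
  th0 <- run$theta[, 1]
  expected <- outer(unname(run$omega), run$time_ms) + th0
  wrap <- function(x) atan2(sin(x), cos(x))
  expect_equal(wrap(run$theta), wrap(expected), tolerance = 1e-9)
  # determinism under fixed seed
  run2 <- simulate_twin(conn, p)
  expect_identical(run$theta, run2$theta)
})

test_that("strong coupling with identical frequencies synchronizes", {
  n <- 10
  w <- matrix(1, n, n); diag(w) <- 0
  d <- matrix(0, n, n)
  conn <- connectome(w, d, velocity_m_s = 7)
  # K strong but dt*K << 1 so the Euler step is stable
  p <- twin_params(K = 5, noise_d = 0, dt = 0.1, duration_ms = 1000,
                   seed = 4, store_every = 1)
  run <- simulate_twin(conn, p, omega = rep(2 * pi * 10 / 1000, n))
  r_end <- twin_kop(run)$r
  expect_gt(tail(r_end, 1), 0.99)
  # classic two-oscillator fixed point: phase difference -> 0
  c2 <- connectome(matrix(c(0, 1, 1, 0), 2), matrix(0, 2, 2))
  run2 <- simulate_twin(c2, twin_params(K = 2, noise_d = 0, dt = 0.1,
                                        duration_ms = 1000, seed = 4,
                                        store_every = 1),
                        omega = rep(0.06, 2))
  dphi <- abs(atan2(sin(run2$theta[1, ] - run2$theta[2, ]),
                    cos(run2$theta[1, ] - run2$theta[2, ])))
  expect_lt(tail(dphi, 1), 1e-3)
})

test_that("dt halving changes the pre-pulse mean KOP by < 2%", {
  conn <- generate_connectome(connectome_spec(n_nodes = 30, seed = 11))
  p1 <- twin_params(K = 0.2, noise_d = 0, dt = 0.2, duration_ms = 1500,
                    seed = 5, store_every = 5)
  p2 <- twin_params(K = 0.2, noise_d = 0, dt = 0.1, duration_ms = 1500,
                    seed = 5, store_every = 10)
  r1 <- mean(twin_kop(simulate_twin(conn, p1))$r)
  r2 <- mean(twin_kop(simulate_twin(conn, p2))$r)
  expect_lt(abs(r1 - r2) / r2, 0.02)
})

test_that("reset schedule: instant set at pulse, remote nodes by delay", {
  conn <- generate_connectome(connectome_spec(n_nodes = 30, seed = 12))
  p <- twin_params(K = 0.2, noise_d = 1, dt = 0.1, duration_ms = 1500,
                   seed = 6, store_every = 1)
  site <- 5
  run <- apply_tms_reset(conn, p, pulse_time_ms = 1000, site = site,
                         instant_radius_mm = 45)
  sched <- run$reset_schedule_ms
  inst <- attr(sched, "instant_nodes")
  expect_true(site %in% inst)
  expect_true(all(sched[inst] == 1000))
  remote <- setdiff(seq_len(30), inst)
  expect_equal(sched[remote], 1000 + conn$delays_ms[remote, site],
               tolerance = 1e-9)
  # KOP of the instantly-reset set equals 1 at the pulse sample
  i_p <- which.min(abs(run$time_ms - 1000))
  expect_equal(kop(run$theta[inst, i_p])$r, 1, tolerance = 1e-9)
  expect_true(all(abs(run$theta[inst, i_p] - pi / 2) < 1e-9))
  # radius covering everything: whole-network r jumps to 1
  runall <- apply_tms_reset(conn, p, pulse_time_ms = 1000, site = site,
                            instant_radius_mm = 1e6)
  expect_equal(twin_kop(runall)$r[i_p], 1, tolerance = 1e-9)
  # identical trajectory before the pulse (same noise stream)
  base <- simulate_twin(conn, p)
  expect_equal(base$theta[, 1:(i_p - 1)], run$theta[, 1:(i_p - 1)])
})

test_that("low-coherence finder locates troughs of an oscillating KOP", {
  fs <- 1000
  tm <- (0:9999) / fs * 1000
  r <- 0.5 + 0.3 * sin(2 * pi * tm / 1000)
  kt <- structure(list(r = r, time_ms = tm, fs = fs), class = "kop_trace")
  cand <- find_low_coherence_times(kt, burn_in_ms = 2000)
  expect_true(length(cand) >= 6)
  expect_true(all(abs((cand - 750) %% 1000) < 30 |
                  abs((cand - 750) %% 1000 - 1000) < 30))
  kc <- structure(list(r = rep(0.5, 5000), time_ms = tm[1:5000], fs = fs),
                  class = "kop_trace")
  expect_error(find_low_coherence_times(kc, burn_in_ms = 1000), "constant")
  expect_error(find_low_coherence_times(kt, burn_in_ms = 20000), "burn-in")
})

test_that("select_subgroup grows with tolerance and includes the target", {
  s <- runif(30, 1, 9)
  om <- assign_frequencies(s, 15, 3)$omega
  g0 <- select_subgroup(om, 7, 0)
  expect_true(7 %in% g0)
  g1 <- select_subgroup(om, 7, 1)
  g3 <- select_subgroup(om, 7, 3)
  expect_true(all(g0 %in% g1) && all(g1 %in% g3))
  expect_equal(sort(g3), 1:30)                   # tolerance >= spread
})

test_that("tune_working_point scores K = 0 at the noise floor", {
  conn <- generate_connectome(connectome_spec(n_nodes = 24, seed = 13))
  p <- twin_params(noise_d = 3, dt = 0.2, duration_ms = 1500, seed = 7,
                   store_every = 5)
  tw <- tune_working_point(conn, K_grid = c(0, 0.3), velocity_grid = 7, p,
                           burn_in_ms = 500)
  expect_equal(nrow(tw$table), 2)
  # K = 0 cell: incoherent, mean r near the 1/sqrt(N) floor
  r0 <- tw$table$mean_r[tw$table$K == 0]
  expect_lt(r0, 0.45)
  expect_true(tw$K %in% c(0, 0.3))
  # reproducible under the same params/seed
  tw2 <- tune_working_point(conn, K_grid = c(0, 0.3), velocity_grid = 7, p,
                            burn_in_ms = 500)
  expect_equal(tw$table$score, tw2$table$score)
})
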