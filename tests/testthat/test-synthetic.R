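test_that("cohort generation is deterministic and shaped as specified", {
  sp <- cohort_spec(n_subjects = 2, n_epochs = 3, seed = 81)
  a <- generate_resting_eeg(sp)
  b <- generate_resting_eeg(sp)
  expect_identical(a$subjects[[2]]$data, b$subjects[[2]]$data)
  expect_equal(dim(a$subjects[[1]]$data), c(3, 32, 2000))
  expect_true(is.na(a$subjects[[1]]$pulse_sample))
  tm <- generate_tms_epochs(cohort_spec(n_subjects = 1, n_epochs = 2,
                                        seed = 81))
  expect_equal(tm$subjects[[1]]$pulse_sample, 501L)
  expect_error(cohort_spec(pulse_ms = 3000), "pulse_ms")
  expect_error(cohort_spec(n_sources = 1), "n_sources")
})

test_that("resting EEG is alpha-dominant with fluctuating synchrony", {
  sp <- cohort_spec(n_subjects = 1, n_epochs = 4, seed = 82)
  co <- generate_resting_eeg(sp)
  x <- co$subjects[[1]]$data[1, 1, ]
  spec <- stats::spec.pgram(stats::ts(x, frequency = 1000), plot = FALSE,
                            taper = 0)
  alpha_p <- mean(spec$spec[spec$freq >= 8 & spec$freq <= 12])
  gamma_p <- mean(spec$spec[spec$freq >= 30 & spec$freq <= 45])
  expect_gt(alpha_p / gamma_p, 1)
  # KOP of the source phases has nonzero windowed std (metastable)
  set.seed(82)
  src <- kopmeta:::run_sources(sp, 2000)
  r <- kop(src$theta)$r
  ms <- sliding_metastability(r, 50, fs = 1000)
  expect_gt(mean(ms$value, na.rm = TRUE), 0.01)
})

test_that("full reset forces cluster-source phase equality at the pulse", {
  sp <- cohort_spec(n_subjects = 1, n_epochs = 1, seed = 83,
                    reset_strength = 1, source_noise = 0, noise_uv = 0)
  set.seed(83)
  src <- kopmeta:::run_sources(sp, 2000, reset = TRUE)
  i_p <- round(sp$pulse_ms * sp$fs / 1000) + 1L
  cl <- src$cluster
  expect_equal(kop(src$theta[cl, i_p])$r, 1, tolerance = 1e-6)
})

test_that("planted-effect strength is monotone over reset_strength", {
  drop_for <- function(rs, seeds) {
    mean(sapply(seeds, function(s) {
      sp <- cohort_spec(n_subjects = 1, n_epochs = 8, seed = s,
                        reset_strength = rs)
      co <- generate_tms_epochs(sp)
      cl <- co$planted[[1]]$cluster_channels
      ph <- extract_phase(co$subjects[[1]], c(8, 12))
      ms <- average_over(sliding_metastability(kop(ph, channels = cl), 50))
      pm <- prepost_means(ms)
      (pm$pre - pm$post) / pm$pre
    }))
  }
  seeds <- 901:904
  d0 <- drop_for(0, seeds)
  d5 <- drop_for(0.5, seeds)
  d1 <- drop_for(1, seeds)
  expect_gt(d5, d0)
  expect_gt(d1, d5)
})

test_that("evoked_amplitude controls exactly the planted deflection", {
  # same seed -> identical sources/noise; the ERP difference must be the
  # deterministic biphasic kernel times the planted topography.  (The
  # phase reset itself also evokes a deterministic component, so the
  # amplitude-0 ERP is not zero -- only the deflection is removed.)
  sp1 <- cohort_spec(n_subjects = 1, n_epochs = 8, seed = 85,
                     reset_strength = 1, evoked_amplitude = 15)
  sp0 <- cohort_spec(n_subjects = 1, n_epochs = 8, seed = 85,
                     reset_strength = 1, evoked_amplitude = 0)
  co1 <- generate_tms_epochs(sp1)
  co0 <- generate_tms_epochs(sp0)
  d <- evoked_response(co1$subjects[[1]]) - evoked_response(co0$subjects[[1]])
  t_ms <- epoch_time_ms(co1$subjects[[1]])
  pred <- 15 * outer(co1$planted[[1]]$evoked_topo,
                     kopmeta:::evoked_kernel(t_ms - 500))
  expect_equal(unname(d), pred, tolerance = 1e-8, ignore_attr = TRUE)
})
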