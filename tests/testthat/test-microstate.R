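test_that("gfp_peaks finds crests of a rectified oscillation", {
  fs <- 1000
  t <- (0:999) / fs
  # two channels in antiphase: GFP = |sin|, crests every half period
  m <- rbind(sin(2 * pi * 10 * t), -sin(2 * pi * 10 * t))
  pk <- gfp_peaks(m)
  n_crests <- length(attr(pk, "peak_index"))
  expect_equal(n_crests, 20, tolerance = 1)      # 10 Hz * 1 s * 2 crests
  # monotone GFP has no interior peaks
  mono <- rbind(seq(0, 1, length.out = 100), -seq(0, 1, length.out = 100))
  expect_error(gfp_peaks(mono), "no GFP peaks")
  # plateau takes its first sample
  g <- c(0, 1, 1, 1, 0)
  mp <- rbind(g, -g)
  expect_equal(attr(gfp_peaks(mp), "peak_index"), 2L)
})

test_that("taahc recovers planted orthogonal templates", {
  set.seed(51)
  n_ch <- 16
  base <- qr.Q(qr(matrix(rnorm(n_ch * 4), n_ch)))[, 1:4]  # orthonormal
  n_maps <- 120
  lab <- sample(1:4, n_maps, replace = TRUE)
  maps <- t(base[, lab]) * sample(c(-1, 1), n_maps, replace = TRUE) +
    matrix(rnorm(n_maps * n_ch, sd = 0.05), n_maps)
  fit <- taahc(maps, k_max = 8)
  tpl <- fit$templates_by_k[["4"]]
  cen <- function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) }
  planted <- t(apply(t(base), 1, cen))
  corr <- abs(tpl %*% t(planted))
  # each planted template matched by some recovered one
  expect_true(all(apply(corr, 2, max) >= 0.95))
  # correlation sum non-increasing as k decreases
  cs <- fit$correlation_sum_by_k[order(as.integer(names(fit$correlation_sum_by_k)))]
  expect_true(all(diff(cs) >= -1e-8))
  # two identical maps at k = 2 give a perfect fit of 2
  two <- rbind(cen(rnorm(n_ch)), 0)
  two[2, ] <- two[1, ]
  fit2 <- taahc(two, k_min = 2, k_max = 2)
  expect_equal(unname(fit2$correlation_sum_by_k[["2"]]), 2, tolerance = 1e-9)
  expect_error(taahc(maps[1:5, ], k_max = 9), "exceeds")
})

test_that("Krzanowski-Lai picks the elbow of a dispersion curve", {
  D <- c(10, 4, 1, 0.95, 0.9, 0.88)
  ks <- 2:7
  n_maps <- 50
  cs <- n_maps - D
  names(cs) <- ks
  k_star <- select_k_krzanowski_lai(cs, n_channels = 30, n_maps = n_maps)
  expect_equal(as.integer(k_star), 4L)
  # flat curve warns and returns earliest maximum
  Dlin <- seq(10, 5, length.out = 6)
  cs2 <- n_maps - Dlin; names(cs2) <- ks
  expect_warning(select_k_krzanowski_lai(cs2, n_channels = 30,
                                         n_maps = n_maps), "flat|elbow")
  expect_error(select_k_krzanowski_lai(cs[1:3], n_channels = 30), "4")
})

test_that("backfit labels, polarity invariance and GEV", {
  set.seed(52)
  n_ch <- 12
  tpl <- qr.Q(qr(matrix(rnorm(n_ch * 3), n_ch)))[, 1:3]
  # data equal to template 2 at every sample -> all labels 2, gev = 1
  m <- matrix(tpl[, 2], n_ch, 40) * rep(runif(40, 0.5, 2), each = n_ch)
  bf <- backfit(m, t(tpl))
  expect_true(all(bf$labels == 2))
  expect_equal(bf$gev, 1, tolerance = 1e-10)
  # global sign flip and positive rescale leave labels unchanged
  bf2 <- backfit(-3.7 * m, t(tpl))
  expect_identical(bf2$labels, bf$labels)
  # white noise: labels roughly uniform over k
  noise <- matrix(rnorm(n_ch * 4000), n_ch)
  bfn <- backfit(noise, t(tpl))
  tab <- table(factor(bfn$labels, levels = 1:3))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  expect_lt(bfn$gev, 0.9)
})

test_that("transition probabilities are row-stochastic with no self-loops", {
  P <- transition_probabilities(c(1, 2, 1, 2), k = 2)
  expect_equal(P[1, 2], 1)
  expect_equal(P[2, 1], 1)
  expect_warning(Pd <- transition_probabilities(c(1, 1, 1), k = 2),
                 "constant")
  expect_equal(attr(Pd, "degenerate_rows"), c(1L, 2L))
  # long uniform sequence: entries near 1/(k-1)
  set.seed(53)
  lab <- sample(1:4, 20000, replace = TRUE)
  P4 <- transition_probabilities(lab, k = 4)
  off <- P4[row(P4) != col(P4)]
  se <- sqrt((1 / 3) * (2 / 3) / (length(lab) / 4))
  expect_true(all(abs(off - 1 / 3) < 3 * se + 0.02))
  expect_equal(unname(rowSums(P4)), rep(1, 4))
})

test_that("post-pulse transition matrices polarize on planted-reset data", {
  sp <- cohort_spec(n_subjects = 1, n_epochs = 12, seed = 54,
                    reset_strength = 1)
  rest <- generate_resting_eeg(cohort_spec(n_subjects = 1, n_epochs = 6,
                                           seed = 54))
  tms <- generate_tms_epochs(sp)
  model <- fit_microstates(rest$subjects[[1]], max_maps = 400)
  bf <- backfit(tms$subjects[[1]], model)
  ps <- tms$subjects[[1]]$pulse_sample
  fs <- tms$subjects[[1]]$fs
  pre <- bf$labels[, (ps - round(0.25 * fs)):(ps - 1)]
  post <- bf$labels[, (ps + 1):(ps + round(0.25 * fs))]
  conc <- function(lbl) {
    P <- suppressWarnings(transition_probabilities(lbl, k = model$k))
    cs <- colSums(P)
    max(cs) - min(cs)
  }
  expect_gt(conc(post), conc(pre))
})
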