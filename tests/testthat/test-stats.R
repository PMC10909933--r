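test_that("prepost_means splits windows around the pulse", {
  tm <- 0:1999
  v <- c(rep(1, 500), rep(0, 1500))    # step 1 -> 0 at the pulse (500 ms)
  pm <- prepost_means(v, pulse_ms = 500, time_ms = tm)
  expect_equal(pm$pre, 1)
  expect_equal(pm$post, 0)
  cst <- prepost_means(rep(0.3, 2000), pulse_ms = 500, time_ms = tm)
  expect_equal(cst$pre, cst$post)
  # NaN inside a window: ignored with count recorded
  v2 <- rep(1, 2000); v2[300:310] <- NaN
  pm2 <- prepost_means(v2, pulse_ms = 500, time_ms = tm)
  expect_equal(pm2$n_pre, 250 - 11)
  expect_error(prepost_means(v[1:600], pulse_ms = 500, time_ms = tm[1:600]),
               "exceed")
})

test_that("shapiro_wilk wraps the test and rejects degenerate input", {
  set.seed(71)
  p_norm <- mean(replicate(100, shapiro_wilk(rnorm(20))$p > 0.05))
  expect_gte(p_norm, 0.9)
  bimodal <- c(rep(0, 10), rep(100, 10)) + rnorm(20, sd = 0.1)
  expect_lt(shapiro_wilk(bimodal)$p, 0.01)
  expect_error(shapiro_wilk(c(1, 2)), "n >= 3")
  expect_error(shapiro_wilk(rep(5, 10)), "constant")
})

test_that("all-decreasing 6-pair case gives exact p = 1/64 and T = 0", {
  pre <- c(5, 6, 7, 8, 9, 10)
  post <- pre - c(1, 2, 3, 1.5, 2.5, 0.5)
  w <- wilcoxon_signed_rank(pre, post, "less")
  expect_equal(w$T, 0)
  expect_equal(w$p, 1 / 64)
  expect_true(w$exact)
})

test_that("exact p equals full 2^n enumeration for random paired data", {
  set.seed(72)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    pre <- rnorm(n)
    post <- pre + rnorm(n)
    dir <- sample(c("less", "greater"), 1)
    w <- wilcoxon_signed_rank(pre, post, dir)
    o <- wilcoxon_enum_oracle(pre, post, dir)
    expect_equal(w$T, o$T)
    expect_equal(w$p, o$p, tolerance = 1e-12)
    # with ties from rounding
    post_t <- pre + round(rnorm(n), 0) + 0.5
    wt <- wilcoxon_signed_rank(pre, post_t, dir)
    ot <- wilcoxon_enum_oracle(pre, post_t, dir)
    expect_equal(wt$p, ot$p, tolerance = 1e-12)
  }
})

test_that("discrete one-tailed p-values overlap: p_less + p_greater >= 1", {
  set.seed(73)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    pre <- rnorm(n); post <- pre + rnorm(n)
    pl <- wilcoxon_signed_rank(pre, post, "less")$p
    pg <- wilcoxon_signed_rank(pre, post, "greater")$p
    expect_gte(pl + pg, 1 - 1e-12)
  }
})

test_that("p is monotone when differences strengthen toward the alternative", {
  set.seed(74)
  pre <- rnorm(10)
  post <- pre - abs(rnorm(10))          # all decreased
  p1 <- wilcoxon_signed_rank(pre, post, "less")$p
  p2 <- wilcoxon_signed_rank(pre, post - 1, "less")$p
  expect_lte(p2, p1 + 1e-12)
  # mixed signs: pushing one positive difference negative cannot raise p
  post3 <- pre + c(rep(-1, 8), 2, 1.5)
  post4 <- post3; post4[9] <- pre[9] - 0.5
  expect_lte(wilcoxon_signed_rank(pre, post4, "less")$p,
             wilcoxon_signed_rank(pre, post3, "less")$p + 1e-12)
})

test_that("normal approximation is sane for n > 25", {
  set.seed(75)
  pre <- rnorm(40)
  post <- pre - abs(rnorm(40))
  w <- wilcoxon_signed_rank(pre, post, "less")
  expect_false(w$exact)
  expect_lt(w$p, 1e-6)
  wg <- wilcoxon_signed_rank(pre, post, "greater")
  expect_gt(wg$p, 0.999)
})

test_that("type-I error of the exact test is controlled at n = 20", {
  set.seed(76)
  rej <- replicate(400, {
    d <- sample(c(-1, 1), 20, replace = TRUE) * abs(rnorm(20))
    wilcoxon_signed_rank(rep(0, 20), d, "less")$p < 0.05
  })
  expect_lte(mean(rej), 0.07)
})

test_that("run_stats_battery shapes results like the effects table", {
  set.seed(77)
  mk_trace <- function(drop) {
    v <- rep(0.04, 2000)
    v[501:750] <- 0.04 - drop
    v[1:250] <- 0.035                    # reference window lower than pre
    structure(list(value = v, time_ms = 0:1999, pulse_sample = 501L,
                   fs = 1000, kind = "kop_std"), class = "meta_trace")
  }
  traces <- lapply(1:12, function(i) mk_trace(0.01 + 0.002 * rnorm(1)))
  tb <- prepost_table(traces, pulse_ms = 500, measure = "metastability",
                      band = c(8, 12), group = "group1")
  res <- run_stats_battery(tb)
  expect_setequal(res$effect,
                  c("decrease_after", "increase_before", "increase_after"))
  dec <- res[res$effect == "decrease_after", ]
  expect_true(dec$significant)
  inc <- res[res$effect == "increase_after", ]
  expect_false(inc$significant)
  expect_true(all(c("T", "p", "p_holm", "shapiro_p") %in% names(res)))
  expect_equal(res$band[1], "8-12")
})
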