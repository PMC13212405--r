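test_that("Ljung-Box detects strong alternation and matches the hand formula", {
  r <- rep(c(-1, 1), 20)
  lb <- ljung_box(r, 10)
  expect_lt(lb$p, 1e-10)
  set.seed(41)
  for (i in 1:100) {
    n <- sample(20:80, 1)
    h <- sample(1:10, 1)
    r <- rnorm(n)
    lb <- ljung_box(r, h)
    expect_equal(lb$Q, bf_lb_Q(r, h), tolerance = 1e-10)
    expect_equal(lb$p, pchisq(bf_lb_Q(r, h), h, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_error(ljung_box(rnorm(5), 4), "n >= h")
  deg <- ljung_box(rep(2, 30), 5)
  expect_true(deg$degenerate)
})

test_that("the t test honours symmetry and degenerate conventions", {
  expect_equal(t_zero_mean(c(-1, 1, -1, 1)), 1)
  expect_equal(t_zero_mean(rep(0, 10)), 1)
  expect_equal(t_zero_mean(rep(0.3, 10)), 0)
  set.seed(42)
  power <- mean(replicate(300, t_zero_mean(rnorm(60, mean = 0.5)) < 0.05))
  expect_gte(power, 0.9)
})

test_that("the HAC mean test reduces to the plain t test for iid data", {
  expect_equal(newey_west_mean_p(c(-2, 1, 1, -1, 2, -1, 1, -1)), 1)
  set.seed(43)
  agree <- replicate(200, {
    r <- rnorm(200)
    abs(newey_west_mean_p(r, L = 3) - t_zero_mean(r))
  })
  # the L-weighted autocovariances vanish in expectation, so the two
  # p-values coincide closely for the vast majority of draws
  expect_lt(median(agree), 0.02)
  expect_gte(mean(agree < 0.05), 0.90)
  expect_lt(max(agree), 0.15)
})

test_that("the plain HAC estimator matches the sandwich reference", {
  skip_if_not_installed("sandwich")
  set.seed(44)
  for (i in 1:20) {
    r <- as.numeric(arima.sim(list(ar = 0.5), 60))
    L <- sample(1:6, 1)
    v <- sandwich::NeweyWest(lm(r ~ 1), lag = L, prewhite = FALSE,
                             adjust = FALSE)[1, 1]
    z <- mean(r) / sqrt(v)
    expect_equal(newey_west_mean_p(r, L), 2 * pnorm(-abs(z)),
                 tolerance = 1e-12)
  }
})

test_that("HAC corrects the size that the naive t test loses to autocorrelation", {
  set.seed(45)
  res <- replicate(400, {
    r <- as.numeric(arima.sim(list(ar = 0.6), 60))
    c(naive = t_zero_mean(r) < 0.05,
      hac = newey_west_mean_p(r, reference = "t", prewhiten = TRUE) < 0.05)
  })
  expect_gte(mean(res["naive", ]), 0.10)
  expect_lt(mean(res["hac", ]), mean(res["naive", ]))
  expect_lte(mean(res["hac", ]), 0.12)
})

test_that("the block bootstrap honours degenerate input and seeding", {
  expect_equal(block_bootstrap_mean_p(rep(0, 40), 4, 500, seed = 1), 1)
  r <- rnorm(60)
  a <- block_bootstrap_mean_p(r, 4, 1000, seed = 7)
  b <- block_bootstrap_mean_p(r, 4, 1000, seed = 7)
  expect_identical(a, b)
  expect_error(block_bootstrap_mean_p(rnorm(10), 10, 500, 1), "block length")
  expect_error(block_bootstrap_mean_p(rnorm(10), 4, 50, 1), "B >= 200")
})

test_that("the block bootstrap is calibrated on iid null residuals", {
  set.seed(46)
  rej <- mean(replicate(500,
    block_bootstrap_mean_p(rnorm(60), 4, 2000,
                           seed = sample.int(1e6, 1)) < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.08)
})

test_that("bootstrap resample means respect block truncation", {
  # n not divisible by b exercises the truncated-last-block path: a
  # zero-mean constant series must still give p = 1, and a constant
  # nonzero series (certain bias) the smallest attainable p
  expect_equal(block_bootstrap_mean_p(rep(0, 37), 5, 500, seed = 2), 1)
  expect_equal(block_bootstrap_mean_p(rep(1, 37), 5, 500, seed = 2),
               1 / 501)
})

test_that("routing separates independent from autocorrelated residuals", {
  cfg <- stats_config(boot_B = 500)
  set.seed(47)
  routes <- replicate(200, {
    a <- assess_gap_bias(rnorm(60), cfg, gap_id = sample.int(1e6, 1))
    a$route
  })
  expect_gte(mean(routes == "independent"), 0.9)
  set.seed(48)
  routes <- replicate(200, {
    r <- as.numeric(arima.sim(list(ar = 0.7), 60))
    assess_gap_bias(r, cfg, gap_id = sample.int(1e6, 1))$route
  })
  expect_gte(mean(routes == "autocorrelated"), 0.8)
})

test_that("the conservative final p dominates both component p-values", {
  cfg <- stats_config(boot_B = 500)
  set.seed(49)
  for (i in 1:50) {
    r <- as.numeric(arima.sim(list(ar = 0.7), sample(25:72, 1)))
    a <- assess_gap_bias(r, cfg, gap_id = i)
    if (a$route == "autocorrelated") {
      expect_gte(a$final_p, a$hac_p)
      expect_gte(a$final_p, a$boot_p)
      expect_true(is.na(a$t_p))
    } else {
      expect_true(is.na(a$hac_p) && is.na(a$boot_p))
      expect_equal(a$final_p, a$t_p)
    }
    expect_true(all(c(a$lb_p, a$final_p) >= 0 & c(a$lb_p, a$final_p) <= 1))
  }
})

test_that("detection power rises monotonically with the injected offset", {
  cfg <- stats_config(boot_B = 500)
  offsets <- c(0, 0.25, 0.5, 1.0)
  set.seed(50)
  base <- matrix(rnorm(200 * 60), 200)      # common random numbers
  ids <- matrix(sample.int(1e6, 200 * 4), 200)
  rates <- vapply(seq_along(offsets), function(k) {
    mean(vapply(1:200, function(i)
      !assess_gap_bias(base[i, ] + offsets[k], cfg, gap_id = ids[i, k])$unbiased,
      TRUE))
  }, 0)
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.12)
  expect_gt(rates[4], 0.99)
})

test_that("perfect imputations are never flagged biased", {
  a <- assess_gap_bias(rep(0, 40), stats_config(boot_B = 500), gap_id = 1)
  expect_true(a$unbiased)
  expect_true(a$degenerate)
  expect_equal(a$final_p, 1)
})

test_that("bias summaries report the documented percentages", {
  res <- data.frame(gap_id = 1:46, model = "m",
                    unbiased = c(rep(TRUE, 42), rep(FALSE, 4)))
  s <- summarize_bias(res)
  expect_equal(s$n_gaps, 46)
  expect_equal(s$n_unbiased, 42)
  expect_equal(s$pct_unbiased, 91.3)    # 42 of 46 at one-decimal granularity
  expect_equal(summarize_bias(res[res$unbiased, ])$pct_unbiased, 100.0)
  res$unbiased <- FALSE
  expect_equal(summarize_bias(res)$pct_unbiased, 0.0)
})
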