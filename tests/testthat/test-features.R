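test_that("first differencing matches its definition and propagates missing", {
  expect_equal(difference(c(1, 3, 2)), c(2, -1))
  expect_equal(difference(rep(5, 10)), rep(0, 9))
  x <- c(1, 2, 3, 4, NA, 6, 7)
  d <- difference(x)
  expect_true(is.na(d[4]) && is.na(d[5]))
  expect_equal(d[c(1:3, 6)], c(1, 1, 1, 1))
  expect_error(difference(1), "at least 2")
  # cumulative summation reconstructs any complete series
  set.seed(1)
  z <- rnorm(50)
  expect_equal(z[1] + c(0, cumsum(difference(z))), z, tolerance = 1e-12)
})

test_that("cross-correlation recovers self- and shifted relationships", {
  set.seed(2)
  dx <- rnorm(500)
  self <- cross_correlation(dx, dx)
  expect_equal(self$r[self$lag == 0], 1)
  dy <- c(rep(NA, 3), dx[1:497])  # dy(t) = dx(t-3)
  cc <- cross_correlation(dx, dy)
  expect_equal(cc$r[cc$lag == 3], 1)
  expect_equal(cc$lag[which.max(abs(cc$r))], 3)
})

test_that("independent white noise shows no spurious correlation", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    cc <- cross_correlation(rnorm(5000), rnorm(5000))
    max(abs(cc$r)) < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("undefined lags are flagged rather than reported", {
  cc <- cross_correlation(rnorm(40), rnorm(40), min_pairs = 30)
  expect_true(all(cc$undefined[cc$n_pairs < 30]))
  cc0 <- cross_correlation(rep(1, 100), rnorm(100))
  expect_true(all(cc0$undefined))
  expect_true(all(is.na(cc0$r)))
})

test_that("cross-correlation is invariant to affine rescaling", {
  set.seed(3)
  dx <- rnorm(300); dy <- 0.5 * dx + rnorm(300)
  a <- cross_correlation(dx, dy)
  b <- cross_correlation(10 + 3 * dx, dy)
  expect_equal(a$r, b$r, tolerance = 1e-12)
})

test_that("predictor selection orders by peak correlation with tie rules", {
  st <- generate_station(synthetic_config(n_hours = 4000, seed = 5))
  cc <- ccf_table(st)
  sel <- select_predictors(cc, threshold = 0.2)
  expect_true("NO" %in% sel)
  expect_false("SO2" %in% sel)   # uncoupled channel
  all_sel <- select_predictors(cc, threshold = 0)
  expect_setequal(all_sel, unique(cc$variable))
  expect_length(select_predictors(cc, threshold = 1.1), 0)
})

test_that("z-score normalization round-trips and fixes the n-1 convention", {
  st <- make_series(runif(100, 0.2, 1))
  norm <- fit_normalizer(st, c("CO", "NO2"))
  x <- get_channel(st, "CO")
  z <- apply_normalizer(x, norm, "CO")
  expect_equal(invert_normalizer(z, norm, "CO"), x, tolerance = 1e-12)
  expect_equal(apply_normalizer(norm$mu[["CO"]], norm, "CO"), 0)
  # x = (0, 10): sample (n-1) sd is sqrt(50), so z = -+ 1/sqrt(2)
  co <- rep(c(0, 10), 25)
  st2 <- make_series(co)
  n2 <- fit_normalizer(st2, "CO", train_idx = 1:2)
  expect_equal(apply_normalizer(c(0, 10), n2, "CO"),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("degenerate variables are rejected by the normalizer", {
  st <- make_series(rep(0.7, 50))
  expect_error(fit_normalizer(st, "CO"), "zero variance")
})

test_that("window and lag-row construction counts match the feasibility argument", {
  st <- make_series(runif(100, 0.2, 1))
  norm <- fit_normalizer(st, c("CO", "NO2", "NO", "TEMP", "RH"))
  nser <- apply_normalizer(st, norm)
  w <- build_windows(nser, c("NO2", "NO"), window = 48)
  expect_equal(dim(w$x)[1], 52)          # targets at hours 49..100
  expect_equal(w$t_idx, 49:100)
  lr <- build_lag_rows(nser)
  expect_equal(nrow(lr), 52)
  expect_equal(lr$t_idx, 49:100)
  # fully missing CO -> no samples
  st_na <- make_series(rep(NA_real_, 100))
  w0 <- build_windows(st_na, c("NO2", "NO"), window = 48)
  expect_equal(dim(w0$x)[1], 0)
  expect_equal(nrow(build_lag_rows(st_na)), 0)
})

test_that("window blocks carry the correct values in the correct order", {
  st <- make_series(seq(1, 10, length.out = 100))
  w <- build_windows(st, "NO2", window = 48)
  co <- get_channel(st, "CO")
  # sample for target t: window rows are co[t-48 .. t-1]
  k <- 5
  t <- w$t_idx[k]
  expect_equal(w$x[k, , "CO"], co[(t - 48):(t - 1)])
  expect_equal(w$y[k], co[t])
  no2 <- get_channel(st, "NO2")
  expect_equal(w$x[k, , "NO2"], no2[(t - 48):(t - 1)])
  # at_target mode holds the exogenous value at t across all steps
  wa <- build_windows(st, "NO2", window = 48, exog_mode = "at_target")
  expect_equal(wa$x[k, , "NO2"], rep(no2[wa$t_idx[k]], 48))
})

test_that("missing lag cells exclude exactly the affected rows", {
  co <- runif(120, 0.2, 1)
  co[60] <- NA  # CO(t-24) missing for t = 84
  st <- make_series(co)
  lr <- build_lag_rows(st)
  expect_false(84 %in% lr$t_idx)
  expect_false(60 %in% lr$t_idx)           # its own target too
  expect_true(100 %in% lr$t_idx)
})

test_that("no supervised sample references a timestamp inside an artificial gap", {
  set.seed(8)
  st <- make_series(runif(800, 0.2, 1))
  gs <- inject_artificial_gaps(st, injection_plan(n_gaps = 3, seed = 2))
  gap_idx <- unlist(lapply(seq_len(nrow(gs$gaps)), function(i)
    gs$gaps$start_idx[i]:gs$gaps$end_idx[i]))
  w <- build_windows(gs$series, c("NO2", "NO"), exclusions = gs)
  for (k in seq_along(w$t_idx))
    expect_length(intersect((w$t_idx[k] - 48):w$t_idx[k], gap_idx), 0)
  lr <- build_lag_rows(gs$series, exclusions = gs)
  for (t in lr$t_idx)
    expect_length(intersect(c(t, t - c(12, 24, 36, 48)), gap_idx), 0)
})

test_that("every admissible window target is also an admissible lag-row target", {
  # lag rows need a subset of the cells a full window needs, so the window
  # targets are contained in the row targets (and rows are at least as many)
  set.seed(9)
  for (i in 1:10) {
    co <- runif(200, 0.2, 1)
    co[sample(200, 30)] <- NA
    st <- make_series(co, seed = i)
    w <- build_windows(st, c("NO2", "NO", "TEMP", "RH"),
                       exog_mode = "at_target")
    lr <- build_lag_rows(st)
    expect_true(all(w$t_idx %in% lr$t_idx))
    expect_gte(nrow(lr), dim(w$x)[1])
  }
})
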