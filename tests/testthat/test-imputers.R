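# Helpers to fabricate supervised samples directly.
fake_lag_rows <- function(n, target) {
  set.seed(17)
  df <- data.frame(t_idx = seq_len(n) + 48,
                   CO_lag12 = rnorm(n), CO_lag24 = rnorm(n),
                   CO_lag36 = rnorm(n), CO_lag48 = rnorm(n),
                   NO2 = rnorm(n), NO = rnorm(n), TEMP = rnorm(n),
                   RH = rnorm(n), target = target)
  attr(df, "lags") <- c(12L, 24L, 36L, 48L)
  attr(df, "exog") <- c("NO2", "NO", "TEMP", "RH")
  class(df) <- c("lag_feature_rows", "data.frame")
  df
}

fake_windows <- function(n, target, T_ = 24, d = 2) {
  set.seed(18)
  list(x = array(rnorm(n * T_ * d), c(n, T_, d),
                 dimnames = list(NULL, NULL, c("CO", "NO2"))),
       y = target, t_idx = seq_len(n) + T_, predictors = "NO2",
       window = T_, exog_mode = "window")
}

test_that("boosted trees drive predictions to a constant target", {
  rows <- fake_lag_rows(200, rep(0, 200))
  m <- train_gbt(rows, seed = 1)
  X <- as.matrix(rows[m$features])
  p <- predict(m$fit, xgboost::xgb.DMatrix(X))
  expect_lt(max(abs(p)), 1e-6)
})

test_that("boosted trees fit a noiseless seasonal signal almost exactly", {
  cfg <- noiseless_config(3000)
  st <- generate_station(cfg)
  norm <- fit_normalizer(st, c("CO", "NO2", "NO", "TEMP", "RH"))
  lr <- build_lag_rows(apply_normalizer(st, norm))
  m <- train_gbt(lr, norm = norm, seed = 2)
  p <- predict(m$fit, xgboost::xgb.DMatrix(as.matrix(lr[m$features])))
  r2 <- 1 - sum((p - lr$target)^2) / sum((lr$target - mean(lr$target))^2)
  expect_gt(r2, 0.99)
})

test_that("tree training is reproducible and guards its preconditions", {
  rows <- fake_lag_rows(150, rnorm(150))
  a <- train_gbt(rows, seed = 5)
  b <- train_gbt(rows, seed = 5)
  X <- xgboost::xgb.DMatrix(as.matrix(rows[a$features]))
  expect_identical(predict(a$fit, X), predict(b$fit, X))
  expect_error(train_gbt(fake_lag_rows(50, rnorm(50))), ">= 100")
})

test_that("network training drives predictions toward a constant target", {
  w <- fake_windows(600, rep(0, 600))
  m <- train_network(w, net_spec("rnn", epochs = 5, seed = 3,
                                 val_fraction = 0))
  p <- cogapfill:::net_forward(m$fit, w$x, m$spec)$pred
  expect_lt(mean(abs(p)), 0.05)
})

test_that("networks learn a noiseless seasonal signal to high one-step accuracy", {
  cfg <- noiseless_config(2000)
  st <- generate_station(cfg)
  norm <- fit_normalizer(st, c("CO", "NO2"))
  w <- build_windows(apply_normalizer(st, norm), "NO2", window = 48)
  m <- train_network(w, net_spec("lstm", epochs = 25, seed = 4,
                                 max_train_samples = 1024, patience = 10),
                     norm = norm)
  p <- cogapfill:::net_forward(m$fit, w$x, m$spec)$pred
  rmse <- sqrt(mean((p - w$y)^2))
  expect_lt(rmse, 0.1 * sd(w$y))
})

test_that("network training is reproducible under a fixed seed", {
  w <- fake_windows(600, rnorm(600))
  spec <- net_spec("lstm", epochs = 2, seed = 9)
  a <- train_network(w, spec)
  b <- train_network(w, spec)
  pa <- cogapfill:::net_forward(a$fit, w$x, a$spec)$pred
  pb <- cogapfill:::net_forward(b$fit, w$x, b$spec)$pred
  expect_equal(pa, pb, tolerance = 1e-6)
  expect_error(train_network(fake_windows(100, rnorm(100))), ">= 500")
})

test_that("recursive imputation returns one value per gap hour with flags", {
  cfg <- noiseless_config(2500)
  st <- generate_station(cfg)
  gs <- inject_artificial_gaps(st, injection_plan(n_gaps = 2, seed = 6))
  norm <- fit_normalizer(gs$series, c("CO", "NO2", "NO", "TEMP", "RH"))
  lr <- build_lag_rows(apply_normalizer(gs$series, norm), exclusions = gs)
  m <- train_gbt(lr, norm = norm, seed = 7)
  for (i in 1:2) {
    gap <- gs$gaps[i, ]
    imp <- impute_gap(m, gs$series, gap)
    expect_equal(nrow(imp), gap$duration_h)
    expect_true(all(is.finite(imp$imputed_ppm)))
    expect_identical(imp$timestamp,
                     gs$series$time[gap$start_idx:gap$end_idx])
    # the 12-h lag falls inside the gap after hour 12
    expect_true(any(imp$used_imputed_lags))
    expect_false(imp$used_imputed_lags[1])
  }
  # degenerate zero-length gap
  empty <- impute_gap(m, gs$series, list(start_idx = 10, end_idx = 9,
                                         gap_id = 1L))
  expect_equal(nrow(empty), 0)
})

test_that("imputation never looks at observations after the gap", {
  cfg <- noiseless_config(2500)
  st <- generate_station(cfg)
  gs <- inject_artificial_gaps(st, injection_plan(n_gaps = 1, seed = 11))
  norm <- fit_normalizer(gs$series, c("CO", "NO2", "NO", "TEMP", "RH"))
  nser <- apply_normalizer(gs$series, norm)
  m <- train_gbt(build_lag_rows(nser, exclusions = gs), norm = norm, seed = 7)
  w <- build_windows(nser, c("NO2", "NO"), exclusions = gs)
  mn <- train_network(w, net_spec("rnn", epochs = 2, seed = 8), norm = norm)
  gap <- gs$gaps[1, ]
  perturbed <- gs$series
  after <- (gap$end_idx + 1):n_hours(perturbed)
  perturbed$data$CO[after] <- perturbed$data$CO[after] + 100
  for (model in list(m, mn)) {
    a <- impute_gap(model, gs$series, gap)
    b <- impute_gap(model, perturbed, gap)
    expect_identical(a$imputed_ppm, b$imputed_ppm)
  }
})

test_that("imputations de-normalize coherently to ppm", {
  cfg <- noiseless_config(2500)
  st <- generate_station(cfg)
  gs <- inject_artificial_gaps(st, injection_plan(n_gaps = 1, seed = 12))
  norm <- fit_normalizer(gs$series, c("CO", "NO2", "NO", "TEMP", "RH"))
  m <- train_gbt(build_lag_rows(apply_normalizer(gs$series, norm),
                                exclusions = gs), norm = norm, seed = 3)
  gap <- gs$gaps[1, ]
  imp <- impute_gap(m, gs$series, gap)
  z <- apply_normalizer(imp$imputed_ppm, norm, "CO")
  expect_equal(invert_normalizer(z, norm, "CO"), imp$imputed_ppm,
               tolerance = 1e-9)
  # warm-up precondition is enforced
  expect_error(impute_gap(m, gs$series, list(start_idx = 10, end_idx = 40,
                                             gap_id = 9L)),
               "warm-up|history")
})
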