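# Fixture builders and independent brute-force oracles used across tests.

# Station series with a prescribed CO vector and non-degenerate exogenous
# channels (deterministic given `seed`).
make_series <- function(co, seed = 1) {
  n <- length(co)
  set.seed(seed)
  tt <- as.POSIXct("2015-01-01 00:00:00", tz = "UTC") + 3600 * (seq_len(n) - 1)
  hod <- as.numeric(format(tt, "%H"))
  data <- data.frame(
    CO = co,
    NO = 20 + 5 * sin(2 * pi * hod / 24) + rnorm(n),
    NO2 = 25 + 4 * cos(2 * pi * hod / 24) + rnorm(n),
    NOX = 45 + 8 * sin(2 * pi * hod / 24) + rnorm(n),
    O3 = 30 - 3 * sin(2 * pi * hod / 24) + rnorm(n),
    SO2 = 5 + rnorm(n),
    PM = 30 + rnorm(n),
    TEMP = 26 + 4 * cos(2 * pi * (hod - 14) / 24) + rnorm(n, sd = 0.5),
    RH = 70 - 10 * cos(2 * pi * (hod - 14) / 24) + rnorm(n, sd = 2),
    WS = 2.5 + rnorm(n, sd = 0.3)
  )
  station_series(tt, data)
}

# Fully deterministic (noise-free) generator configuration.
noiseless_config <- function(n_hours = 4000L, seed = 1L) {
  synthetic_config(
    n_hours = n_hours, seed = seed, ar_coef = 0, noise_sd = 0,
    couplings = list(
      NO  = list(base = 20, gain = 30, noise_sd = 0),
      NO2 = list(base = 25, gain = 25, noise_sd = 0),
      NOX = list(base = 45, gain = 55, noise_sd = 0),
      O3  = list(base = 30, gain = -20, noise_sd = 0),
      SO2 = list(base = 5, gain = 0, noise_sd = 0),
      PM  = list(base = 30, gain = 10, noise_sd = 0)
    ),
    gap_rate = 0, exog_gap_rate = 0)
}

# Brute-force maximal-run scan over a logical missingness mask.
bf_runs <- function(miss) {
  out <- NULL
  i <- 1L; n <- length(miss)
  while (i <= n) {
    if (miss[i]) {
      j <- i
      while (j < n && miss[j + 1L]) j <- j + 1L
      out <- rbind(out, c(start = i, end = j, len = j - i + 1L))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Brute-force accuracy metrics.
bf_score <- function(o, p) {
  n <- length(o)
  ae <- 0; se <- 0
  for (i in seq_len(n)) {
    ae <- ae + abs(o[i] - p[i]); se <- se + (o[i] - p[i])^2
  }
  ob <- sum(o) / n
  sst <- sum((o - ob)^2)
  list(mae = ae / n, rmse = sqrt(se / n),
       r2 = if (sst == 0) NA_real_ else 1 - se / sst)
}

# Brute-force Kruskal-Wallis H with tie correction.
bf_kw_H <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  N <- length(x)
  rk <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Brute-force Ljung-Box Q.
bf_lb_Q <- function(r, h) {
  n <- length(r)
  rc <- r - mean(r)
  denom <- sum(rc^2)
  rho <- vapply(1:h, function(k) sum(rc[1:(n - k)] * rc[(1 + k):n]) / denom, 0)
  n * (n + 2) * sum(rho^2 / (n - 1:h))
}

# Brute-force OLS slope/intercept via the normal equations.
bf_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# Exhaustive validity check of an artificial gap set against the
# pre-injection series. Returns character(0) when all constraints hold.
check_gap_set <- function(gap_set, pre_series, plan) {
  msgs <- character(0)
  g <- gap_set$gaps
  if (!nrow(g)) return(msgs)
  n <- n_hours(pre_series)
  pre_na <- is.na(as.matrix(pre_series$data))
  for (i in seq_len(nrow(g))) {
    s <- g$start_idx[i]; e <- g$end_idx[i]; len <- g$duration_h[i]
    if (len < plan$min_len || len > plan$max_len || len != round(len))
      msgs <- c(msgs, sprintf("gap %d: bad length %s", i, len))
    req <- if (plan$require_complete_exog) colnames(pre_na)
           else plan$target_variable
    span <- (s - plan$buffer_h):e
    if (min(span) < 1 || any(pre_na[span, req]))
      msgs <- c(msgs, sprintf("gap %d: incomplete region or buffer", i))
    for (j in seq_len(nrow(g)))
      if (j != i && s <= g$end_idx[j] && e >= g$start_idx[j])
        msgs <- c(msgs, sprintf("gaps %d and %d overlap", i, j))
  }
  msgs
}
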