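#' Configuration for the synthetic station generator
#'
#' Defines the statistical structure of a simulated hourly air-quality
#' station: a carbon monoxide signal with a double-peaked (rush-hour)
#' diurnal profile, a weekly term and short-memory AR(1) noise; exogenous
#' channels coupled to the CO signal at lag 0 (O3 with negative gain);
#' meteorology with a single diurnal harmonic; and mechanism-driven gaps
#' whose duration distribution follows the four standard bins (short 1-24 h,
#' medium 25-72 h, long 73-120 h, very long 121-168 h).
#'
#' Defaults describe a two-year urban traffic-exposed station: CO around
#' 0.6 ppm with diurnal peaks near 08:00 and 20:00, AR(1) persistence 0.6,
#' innovation sd 0.10 ppm, strong lag-0 coupling of the nitrogen family,
#' anticorrelated O3, an uncoupled SO2 channel, and MAR gaps whose start
#' probability rises with relative humidity.
#'
#' @param n_hours number of hourly rows (>= 168).
#' @param seed master integer seed; one child stream per channel is derived
#'   from it, so adding a channel never perturbs the others.
#' @param co_base baseline CO concentration (ppm).
#' @param diurnal_amps amplitudes (ppm) of the daily harmonics; harmonic
#'   `j` is `amps[j] * cos(2*pi*j*(hour - peak_hour)/24)`, so the second
#'   harmonic creates the morning/evening double peak.
#' @param peak_hour hour of day (0-23) at which the diurnal harmonics peak.
#' @param weekly_amp amplitude (ppm) of the weekly cosine term.
#' @param ar_coef AR(1) coefficient of the CO stochastic component,
#'   `|ar_coef| < 1`.
#' @param noise_sd innovation standard deviation (ppm) of the AR(1) term.
#' @param couplings named list: for each coupled channel, `list(base=,
#'   gain=, noise_sd=)` giving `channel = base + gain * (CO signal - co_base)
#'   + iid noise`. The O3 gain must be negative.
#' @param mechanism missingness mechanism for generated gaps: `"MAR"`
#'   (start probability increases with observed RH) or `"MCAR"`.
#' @param gap_rate expected mechanism gaps per 1000 h on the CO channel.
#' @param exog_gap_rate expected mechanism gaps per 1000 h on each
#'   non-CO channel.
#' @param gap_len_dist probabilities of the four duration bins
#'   (short/medium/long/very_long); must sum to 1. Lengths are uniform
#'   within a bin.
#' @param mar_covariate observed channel that drives MAR gap starts.
#' @param mar_strength logistic slope of the MAR dependence on the
#'   standardized covariate.
#' @param start first timestamp (UTC).
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_hours = 17520L,
                             seed = 1L,
                             co_base = 0.6,
                             diurnal_amps = c(0.20, 0.15),
                             peak_hour = 8,
                             weekly_amp = 0.05,
                             ar_coef = 0.6,
                             noise_sd = 0.10,
                             couplings = NULL,
                             mechanism = c("MAR", "MCAR"),
                             gap_rate = 1.5,
                             exog_gap_rate = 0.3,
                             gap_len_dist = c(short = 72, medium = 3,
                                              long = 1, very_long = 0) / 76,
                             mar_covariate = "RH",
                             mar_strength = 1.5,
                             start = as.POSIXct("2015-01-01 00:00:00",
                                                tz = "UTC")) {
  mechanism <- match.arg(mechanism)
  if (is.null(couplings)) {
    couplings <- list(
      NO  = list(base = 20,  gain =  30, noise_sd = 3),
      NO2 = list(base = 25,  gain =  25, noise_sd = 4),
      NOX = list(base = 45,  gain =  55, noise_sd = 5),
      O3  = list(base = 30,  gain = -20, noise_sd = 4),
      SO2 = list(base = 5,   gain =   0, noise_sd = 1.5),
      PM  = list(base = 30,  gain =  10, noise_sd = 8)
    )
  }
  cfg <- list(n_hours = as.integer(n_hours), seed = as.integer(seed),
              co_base = co_base, diurnal_amps = diurnal_amps,
              peak_hour = peak_hour, weekly_amp = weekly_amp,
              ar_coef = ar_coef, noise_sd = noise_sd, couplings = couplings,
              mechanism = mechanism, gap_rate = gap_rate,
              exog_gap_rate = exog_gap_rate, gap_len_dist = gap_len_dist,
              mar_covariate = mar_covariate, mar_strength = mar_strength,
              start = start)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (!is_count(cfg$n_hours) || cfg$n_hours < 168)
    stopf("invalid config field n_hours: must be an integer >= 168")
  if (!is.finite(cfg$ar_coef) || abs(cfg$ar_coef) >= 1)
    stopf("invalid config field ar_coef: |ar_coef| must be < 1")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd < 0)
    stopf("invalid config field noise_sd: must be >= 0")
  if (length(cfg$gap_len_dist) != 4 || any(cfg$gap_len_dist < 0) ||
      abs(sum(cfg$gap_len_dist) - 1) > 1e-8)
    stopf("invalid config field gap_len_dist: four probabilities summing to 1")
  if (cfg$gap_rate < 0 || cfg$exog_gap_rate < 0)
    stopf("invalid config field gap_rate: must be >= 0")
  if (!is.null(cfg$couplings$O3) && cfg$couplings$O3$gain > 0)
    stopf("invalid config field couplings: O3 gain must be <= 0")
  for (nm in names(cfg$couplings))
    if (cfg$couplings[[nm]]$noise_sd < 0)
      stopf("invalid config field couplings: %s noise_sd must be >= 0", nm)
  invisible(cfg)
}

# Deterministic CO seasonal template (ppm) at integer hour offsets `h`
# from the start timestamp's hour-of-day origin.
co_seasonal_template <- function(cfg, hour_of_day, hour_abs) {
  daily <- rep(0, length(hour_of_day))
  for (j in seq_along(cfg$diurnal_amps))
    daily <- daily +
      cfg$diurnal_amps[j] * cos(2 * pi * j * (hour_of_day - cfg$peak_hour) / 24)
  weekly <- cfg$weekly_amp * cos(2 * pi * hour_abs / 168)
  cfg$co_base + daily + weekly
}

#' Generate a complete synthetic station series
#'
#' Simulates every channel according to the generative model in
#' [synthetic_config()]: CO is the seasonal template plus a stationary AR(1)
#' process; each coupled pollutant channel is an affine function of the CO
#' signal (seasonal + stochastic, relative to baseline) plus independent
#' noise; TEMP is a single diurnal harmonic, RH is in anti-phase with TEMP
#' and clipped to \[0, 100\]; WS has a weak diurnal cycle. All concentration
#' channels are clipped at 0. The result contains no missing cells.
#'
#' @param config a `synthetic_config`.
#' @return A complete `station_series`.
#' @export
generate_station <- function(config) {
  validate_synthetic_config(config)
  local_rng()
  n <- config$n_hours
  tt <- config$start + 3600 * (seq_len(n) - 1)
  hod <- as.numeric(format(tt, "%H", tz = "UTC"))
  habs <- seq_len(n) - 1

  seasonal <- co_seasonal_template(config, hod, habs)

  # Stationary AR(1) stochastic component, own stream.
  ar <- local({
    set.seed(derive_seed(config$seed, 1L))
    innov <- rnorm(n, sd = config$noise_sd)
    if (config$noise_sd == 0 || config$ar_coef == 0) {
      if (config$ar_coef == 0) innov
      else as.numeric(stats::filter(innov, config$ar_coef, "recursive"))
    } else {
      x <- as.numeric(stats::filter(innov, config$ar_coef, "recursive"))
      # burn-in replacement: start from the stationary distribution
      x[1] <- rnorm(1, sd = config$noise_sd / sqrt(1 - config$ar_coef^2))
      for (t in 2:n) x[t] <- config$ar_coef * x[t - 1] + innov[t]
      x
    }
  })
  co_signal <- seasonal + ar
  data <- data.frame(CO = pmax(co_signal, 0))

  ch_index <- 2L
  for (nm in c("NO", "NO2", "NOX", "O3", "SO2", "PM")) {
    cp <- config$couplings[[nm]]
    set.seed(derive_seed(config$seed, ch_index))
    eps <- if (cp$noise_sd > 0) rnorm(n, sd = cp$noise_sd) else rep(0, n)
    data[[nm]] <- pmax(cp$base + cp$gain * (co_signal - config$co_base) + eps, 0)
    ch_index <- ch_index + 1L
  }

  set.seed(derive_seed(config$seed, 8L))
  temp_noise <- rnorm(n, sd = 0.8)
  data$TEMP <- 26 + 4 * cos(2 * pi * (hod - 14) / 24) + temp_noise
  set.seed(derive_seed(config$seed, 9L))
  # synoptic component: multi-day humid/dry episodes (AR(1), ~50 h memory),
  # on top of the diurnal cycle in anti-phase with temperature
  synoptic <- as.numeric(stats::filter(rnorm(n, sd = 6 * sqrt(1 - 0.98^2)),
                                       0.98, "recursive"))
  rh <- 75 - 15 * cos(2 * pi * (hod - 14) / 24) + synoptic + rnorm(n, sd = 3)
  data$RH <- pmin(pmax(rh, 0), 100)
  set.seed(derive_seed(config$seed, 10L))
  data$WS <- pmax(2.5 + 0.8 * cos(2 * pi * (hod - 15) / 24) +
                    rnorm(n, sd = 0.6), 0)

  station_series(tt, data)
}

# Draw one gap length (hours) from the binned duration distribution.
GAP_BINS <- data.frame(label = c("short", "medium", "long", "very_long"),
                       lo = c(1, 25, 73, 121), hi = c(24, 72, 120, 168),
                       stringsAsFactors = FALSE)

draw_gap_lengths <- function(k, gap_len_dist) {
  bin <- sample.int(4L, k, replace = TRUE, prob = gap_len_dist)
  lo <- GAP_BINS$lo[bin]; hi <- GAP_BINS$hi[bin]
  lo + floor(runif(k) * (hi - lo + 1))
}

#' Inject mechanism-driven gaps into a complete series
#'
#' Masks whole contiguous runs per channel. Under MCAR, gap starts are
#' uniform over time; under MAR, the start probability increases
#' logistically with the standardized observed MAR covariate (default RH) —
#' never with the masked value itself. Gap lengths are drawn from the
#' binned duration distribution of the configuration. Masked values are
#' preserved in a ground-truth table.
#'
#' @param series a complete `station_series`.
#' @param config a `synthetic_config`.
#' @return `list(series = masked station_series, truth = ground-truth
#'   data.frame)` with one truth row per masked cell.
#' @export
inject_mechanism_gaps <- function(series, config) {
  validate_synthetic_config(config)
  local_rng()
  if (anyNA(as.matrix(series$data)))
    stopf("inject_mechanism_gaps requires a complete series")
  n <- n_hours(series)

  if (config$gap_rate == 0 && config$exog_gap_rate == 0)
    return(list(series = series, truth = empty_ground_truth()))

  weights <- rep(1, n)
  if (config$mechanism == "MAR") {
    z <- get_channel(series, config$mar_covariate)
    z <- (z - mean(z)) / stats::sd(z)
    weights <- exp(config$mar_strength * z)
  }

  truth_list <- list()
  data <- series$data
  prov <- series$provenance

  for (ci in seq_along(STATION_CHANNELS)) {
    ch <- STATION_CHANNELS[ci]
    rate <- if (ch == "CO") config$gap_rate else config$exog_gap_rate
    if (rate == 0) next
    set.seed(derive_seed(config$seed, 100L + ci))
    k <- stats::rpois(1, rate * n / 1000)
    if (k == 0) next
    masked <- rep(FALSE, n)
    placed <- 0L
    tries <- 0L
    while (placed < k && tries < 50L * k) {
      tries <- tries + 1L
      len <- draw_gap_lengths(1L, config$gap_len_dist)
      s <- sample.int(n, 1L, prob = weights)
      e <- min(s + len - 1L, n)
      if (any(masked[s:e])) next
      masked[s:e] <- TRUE
      placed <- placed + 1L
    }
    if (placed < k)
      stopf("gap placement failed for %s: placed %d of %d gaps", ch, placed, k)
    idx <- which(masked)
    truth_list[[ch]] <- data.frame(variable = ch,
                                   timestamp = series$time[idx],
                                   value = data[[ch]][idx])
    data[[ch]][idx] <- NA_real_
    prov[idx, ch] <- "mechanism-gap"
  }

  truth <- if (length(truth_list)) do.call(rbind, truth_list)
           else empty_ground_truth()
  rownames(truth) <- NULL
  list(series = station_series(series$time, data, prov), truth = truth)
}
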