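#' First-order differencing of one channel
#'
#' `d(t) = x(t) - x(t-1)`; a difference is missing whenever either operand
#' is missing. Differencing removes the slowly varying level so that
#' cross-correlations reflect short-term co-movement rather than shared
#' trends.
#'
#' @param series a `station_series`, or a plain numeric vector.
#' @param variable channel name (ignored when `series` is a vector).
#' @return numeric vector of length `n - 1` (element `i` is
#'   `x(i+1) - x(i)`).
#' @export
difference <- function(series, variable = NULL) {
  x <- if (inherits(series, "station_series")) get_channel(series, variable)
       else as.numeric(series)
  if (length(x) < 2) stopf("differencing needs at least 2 values")
  x[-1] - x[-length(x)]
}

#' Cross-correlation of a differenced predictor with differenced CO
#'
#' For each lag `tau = 0..max_lag` (hours), the Pearson correlation of
#' `dx(t - tau)` with `dy(t)` over jointly observed pairs — positive lags
#' only, so the predictor always leads (or is contemporaneous with) the
#' target. Lags with fewer than `min_pairs` complete pairs, or with zero
#' variance in either margin, are reported as `NA` and flagged.
#'
#' @param dx differenced predictor sequence.
#' @param dy differenced target (CO) sequence, same length.
#' @param max_lag largest lag in hours (default 25).
#' @param min_pairs minimum jointly observed pairs per lag (default 30).
#' @return data.frame with columns `lag`, `r`, `n_pairs`, `undefined`.
#' @export
cross_correlation <- function(dx, dy, max_lag = 25L, min_pairs = 30L) {
  if (length(dx) != length(dy)) stopf("dx and dy must have equal length")
  n <- length(dx)
  rows <- lapply(0:max_lag, function(tau) {
    if (n - tau < 2)
      return(data.frame(lag = tau, r = NA_real_, n_pairs = 0L,
                        undefined = TRUE))
    a <- dx[seq_len(n - tau)]           # dx(t - tau)
    b <- dy[seq_len(n - tau) + tau]     # dy(t)
    keep <- !is.na(a) & !is.na(b)
    m <- sum(keep)
    if (m < min_pairs || stats::sd(a[keep]) == 0 || stats::sd(b[keep]) == 0)
      return(data.frame(lag = tau, r = NA_real_, n_pairs = m,
                        undefined = TRUE))
    data.frame(lag = tau, r = stats::cor(a[keep], b[keep]), n_pairs = m,
               undefined = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-correlation table for all candidate predictors
#'
#' Differences the target and every candidate channel and computes the
#' lagged cross-correlation of each candidate with the target.
#'
#' @param series a `station_series`.
#' @param target target channel (default `"CO"`).
#' @param predictors candidate channels (default: every other channel).
#' @param max_lag largest lag in hours.
#' @return data.frame with columns `variable`, `lag`, `r`, `n_pairs`,
#'   `undefined`, of class `ccf_table`.
#' @export
ccf_table <- function(series, target = "CO",
                      predictors = setdiff(STATION_CHANNELS, target),
                      max_lag = 25L) {
  dy <- difference(series, target)
  rows <- lapply(predictors, function(v) {
    cbind(variable = v, cross_correlation(difference(series, v), dy, max_lag))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ccf_table", "data.frame")
  out
}

#' Select predictors from a cross-correlation table
#'
#' Keeps every variable whose maximum absolute correlation over the lag
#' range reaches `threshold`, ordered by that maximum (descending; ties
#' broken alphabetically).
#'
#' @param ccf a `ccf_table`.
#' @param threshold minimum `max |r|` to keep a variable (default 0.2).
#' @return character vector of selected variable names.
#' @export
select_predictors <- function(ccf, threshold = 0.2) {
  if (!nrow(ccf)) stopf("empty cross-correlation table")
  peak <- vapply(split(ccf$r, ccf$variable),
                 function(r) if (all(is.na(r))) -Inf else max(abs(r), na.rm = TRUE),
                 0)
  peak <- peak[peak >= threshold]
  names(peak)[order(-peak, names(peak))]
}

#' z-score normalization parameters from a training span
#'
#' Per-variable mean and sample (n-1) standard deviation over the training
#' span, used to standardize model inputs and to restore imputed CO to ppm.
#'
#' @param series a `station_series`.
#' @param variables channels to normalize.
#' @param train_idx integer row indices of the training span (default: all).
#' @return list of class `normalization_params` with `mu` and `sigma`
#'   named vectors.
#' @export
fit_normalizer <- function(series, variables, train_idx = NULL) {
  if (is.null(train_idx)) train_idx <- seq_len(n_hours(series))
  mu <- sigma <- stats::setNames(numeric(length(variables)), variables)
  for (v in variables) {
    x <- get_channel(series, v)[train_idx]
    x <- x[!is.na(x)]
    if (length(x) < 2) stopf("variable %s: need >= 2 observed values", v)
    s <- stats::sd(x)
    if (s == 0) stopf("variable %s has zero variance on the training span", v)
    mu[v] <- mean(x); sigma[v] <- s
  }
  structure(list(mu = mu, sigma = sigma), class = "normalization_params")
}

#' Apply / invert z-score normalization
#'
#' `apply_normalizer` standardizes (missing values preserved);
#' `invert_normalizer` restores original units.
#'
#' @param x numeric vector, or a `station_series` (then every variable in
#'   `params` is transformed).
#' @param params a `normalization_params`.
#' @param variable variable name when `x` is a vector.
#' @return object of the same shape as `x`.
#' @export
apply_normalizer <- function(x, params, variable = NULL) {
  if (inherits(x, "station_series")) {
    for (v in names(params$mu))
      x$data[[v]] <- (x$data[[v]] - params$mu[v]) / params$sigma[v]
    return(x)
  }
  (x - params$mu[[variable]]) / params$sigma[[variable]]
}

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(x, params, variable = NULL) {
  if (inherits(x, "station_series")) {
    for (v in names(params$mu))
      x$data[[v]] <- x$data[[v]] * params$sigma[v] + params$mu[v]
    return(x)
  }
  x * params$sigma[[variable]] + params$mu[[variable]]
}

# Logical mask of hours lying inside any artificial gap of `gap_set`
# (NULL gap_set -> no exclusions).
artificial_gap_mask <- function(n, gap_set) {
  mask <- logical(n)
  if (is.null(gap_set) || !nrow(gap_set$gaps)) return(mask)
  for (i in seq_len(nrow(gap_set$gaps)))
    mask[gap_set$gaps$start_idx[i]:gap_set$gaps$end_idx[i]] <- TRUE
  mask
}

#' Build 48-hour window samples for the recurrent models
#'
#' One supervised sample per admissible target hour `t`: the input block is
#' the `window` hourly values preceding `t` for CO and each selected
#' exogenous channel, the target is CO at `t`. A sample is admissible only
#' when every referenced cell is observed and none lies inside an
#' artificial gap. With `exog_mode = "window"` the exogenous channels enter
#' as full windows; with `"at_target"` each exogenous channel contributes
#' its value at `t`, held constant across the window steps (the
#' contemporaneous-predictor reading of the design).
#'
#' @param series a `station_series` (typically already normalized).
#' @param predictors exogenous channel names.
#' @param window window length in hours (default 48).
#' @param exclusions an `artificial_gap_set` or `NULL`.
#' @param exog_mode `"window"` (default) or `"at_target"`.
#' @return list of class `window_samples`: `x` an array
#'   `n_samples x window x (1 + n_predictors)` (CO first), `y` the target
#'   vector, `t_idx` the target row indices, `predictors`, `exog_mode`.
#' @export
build_windows <- function(series, predictors, window = 48L,
                          exclusions = NULL,
                          exog_mode = c("window", "at_target")) {
  exog_mode <- match.arg(exog_mode)
  n <- n_hours(series)
  vars <- c("CO", predictors)
  m <- as.matrix(series$data[vars])
  excl <- artificial_gap_mask(n, exclusions)
  usable <- !is.na(m) & !excl  # cell usable for any role
  # admissible t: all cells of the block and the target usable
  ok <- rep(TRUE, n)
  ok[seq_len(min(window, n))] <- FALSE
  win_vars <- if (exog_mode == "window") vars else "CO"
  for (v in win_vars) {
    cs <- c(0, cumsum(usable[, v]))
    idx <- (window + 1):n
    ok[idx] <- ok[idx] & (cs[idx] - cs[idx - window] == window)
  }
  ok <- ok & usable[, "CO"]
  if (exog_mode == "at_target")
    for (v in predictors) ok <- ok & usable[, v]
  t_idx <- which(ok)

  x <- array(NA_real_, c(length(t_idx), window, length(vars)),
             dimnames = list(NULL, NULL, vars))
  if (length(t_idx)) {
    off <- outer(t_idx, window:1, `-`)  # [sample, step] row indices
    for (j in seq_along(vars)) {
      v <- vars[j]
      if (v == "CO" || exog_mode == "window")
        x[, , j] <- matrix(m[, v][off], length(t_idx), window)
      else
        x[, , j] <- matrix(m[t_idx, v], length(t_idx), window)
    }
  }
  structure(list(x = x, y = m[t_idx, "CO"], t_idx = t_idx,
                 predictors = predictors, window = window,
                 exog_mode = exog_mode),
            class = "window_samples")
}

#' Build explicit lag-feature rows for the tree model
#'
#' One row per admissible target hour `t` with features
#' `CO(t-12), CO(t-24), CO(t-36), CO(t-48)` and the contemporaneous
#' exogenous values (default `NO2, NO, TEMP, RH`), target `CO(t)`. A row is
#' admissible only when all nine cells are observed and none lies inside an
#' artificial gap.
#'
#' @param series a `station_series` (typically already normalized).
#' @param exclusions an `artificial_gap_set` or `NULL`.
#' @param lags CO lags in hours.
#' @param exog contemporaneous exogenous channels.
#' @return data.frame of class `lag_feature_rows` with columns `t_idx`, the
#'   lag features `CO_lag<k>`, the exogenous features, and `target`.
#' @export
build_lag_rows <- function(series, exclusions = NULL,
                           lags = c(12L, 24L, 36L, 48L),
                           exog = c("NO2", "NO", "TEMP", "RH")) {
  n <- n_hours(series)
  m <- as.matrix(series$data[unique(c("CO", exog))])
  excl <- artificial_gap_mask(n, exclusions)
  co <- ifelse(is.na(m[, "CO"]) | excl, NA_real_, m[, "CO"])
  ex <- m[, exog, drop = FALSE]
  ex[excl, ] <- NA_real_

  maxlag <- max(lags)
  if (n <= maxlag) stopf("series too short for lag features (need > %d h)", maxlag)
  t_all <- (maxlag + 1):n
  feat <- sapply(lags, function(k) co[t_all - k])
  colnames(feat) <- paste0("CO_lag", lags)
  row_ok <- !is.na(co[t_all]) & rowSums(is.na(feat)) == 0 &
    rowSums(is.na(ex[t_all, , drop = FALSE])) == 0
  out <- data.frame(t_idx = t_all[row_ok],
                    feat[row_ok, , drop = FALSE],
                    ex[t_all[row_ok], , drop = FALSE],
                    target = co[t_all[row_ok]])
  rownames(out) <- NULL
  attr(out, "lags") <- lags
  attr(out, "exog") <- exog
  class(out) <- c("lag_feature_rows", "data.frame")
  out
}
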