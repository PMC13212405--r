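#' Gradient-boosted-tree model specification
#'
#' The reference configuration: 600 trees, maximum depth 6, learning rate
#' 0.05, squared-error loss. Dynamic information enters only through the
#' CO lags of the feature rows.
#'
#' @param n_trees,max_depth,learning_rate boosting hyperparameters.
#' @return list of class `gbt_spec`.
#' @export
gbt_spec <- function(n_trees = 600L, max_depth = 6L, learning_rate = 0.05) {
  if (n_trees <= 0 || max_depth <= 0 || learning_rate <= 0)
    stopf("gbt_spec fields must be positive")
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, loss = "squared_error"),
            class = "gbt_spec")
}

#' Recurrent-network specification
#'
#' Two architectures: `"lstm"` (64 then 32 LSTM units, 64 rectified-linear
#' dense units) and `"rnn"` (128 then 64 sigmoid recurrent units, 128
#' rectified-linear dense units), both with a scalar linear output,
#' mean-squared-error loss and Adam optimization. Training length, batch
#' size and early stopping are tunable; the layer sizes are fixed by the
#' architecture.
#'
#' @param family `"lstm"` or `"rnn"`.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param val_fraction fraction of samples held out for early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param max_train_samples cap on training samples (a seeded subsample is
#'   taken above it); `Inf` to use all.
#' @param seed integer seed for initialization, shuffling and the split.
#' @return list of class `net_spec`.
#' @export
net_spec <- function(family = c("lstm", "rnn"), epochs = 30L,
                     batch_size = 64L, lr = 1e-3, val_fraction = 0.1,
                     patience = 5L, max_train_samples = 4096L, seed = 1L) {
  family <- match.arg(family)
  units <- if (family == "lstm") c(64L, 32L) else c(128L, 64L)
  dense_units <- if (family == "lstm") 64L else 128L
  structure(list(family = family, units = units, dense_units = dense_units,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, val_fraction = val_fraction,
                 patience = as.integer(patience),
                 max_train_samples = max_train_samples,
                 seed = as.integer(seed)),
            class = "net_spec")
}

new_trained_imputer <- function(family, fit, norm, predictors, exog_mode,
                                extra = list()) {
  structure(c(list(family = family, fit = fit, norm = norm,
                   predictors = predictors, exog_mode = exog_mode), extra),
            class = "trained_imputer")
}

#' @export
print.trained_imputer <- function(x, ...) {
  cat(sprintf("trained_imputer: %s; predictors: %s\n", x$family,
              paste(x$predictors, collapse = ", ")))
  invisible(x)
}

#' Train the gradient-boosted-tree imputer
#'
#' Fits boosted regression trees on explicit lag-feature rows (normalized
#' CO lags at 12/24/36/48 h plus contemporaneous exogenous values) to
#' predict normalized CO at the target hour.
#'
#' @param rows a `lag_feature_rows` data.frame (normalized).
#' @param spec a `gbt_spec`.
#' @param norm the `normalization_params` used to build `rows`.
#' @param seed integer seed.
#' @return a `trained_imputer`.
#' @export
train_gbt <- function(rows, spec = gbt_spec(), norm = NULL, seed = 1L) {
  if (nrow(rows) < 100) stopf("need >= 100 training rows, got %d", nrow(rows))
  local_rng()
  feats <- setdiff(names(rows), c("t_idx", "target"))
  X <- as.matrix(rows[feats])
  y <- rows$target
  set.seed(seed)
  fit <- xgboost::xgb.train(
    params = list(max_depth = spec$max_depth, eta = spec$learning_rate,
                  objective = "reg:squarederror", nthread = 1,
                  seed = seed),
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = spec$n_trees, verbose = 0)
  new_trained_imputer("gbt", fit, norm, attr(rows, "exog"), "at_target",
                      list(lags = attr(rows, "lags"), features = feats,
                           spec = spec))
}

#' Train a recurrent-network imputer
#'
#' Fits the network of `spec` to predict normalized CO one step ahead from
#' the preceding 48-hour multivariate window, by minibatch Adam on the
#' mean-squared error with early stopping on a held-out validation split.
#'
#' @param samples a `window_samples` object (normalized).
#' @param spec a `net_spec`.
#' @param norm the `normalization_params` used to build `samples`.
#' @return a `trained_imputer` whose `history` records per-epoch losses.
#' @export
train_network <- function(samples, spec = net_spec(), norm = NULL) {
  n <- dim(samples$x)[1]
  if (n < 500) stopf("need >= 500 window samples, got %d", n)
  local_rng()
  set.seed(spec$seed)
  idx <- seq_len(n)
  if (is.finite(spec$max_train_samples) && n > spec$max_train_samples)
    idx <- sort(sample.int(n, spec$max_train_samples))
  x <- samples$x[idx, , , drop = FALSE]
  y <- samples$y[idx]
  n <- length(y)

  n_val <- floor(spec$val_fraction * n)
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  xv <- x[val_idx, , , drop = FALSE]; yv <- y[val_idx]
  xt <- x[tr_idx, , , drop = FALSE]; yt <- y[tr_idx]
  ntr <- length(yt)

  params <- net_init(spec, dim(x)[3])
  state <- adam_init(params)
  best <- list(loss = Inf, params = params)
  bad_epochs <- 0L
  history <- data.frame(epoch = integer(0), train_mse = numeric(0),
                        val_mse = numeric(0))

  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(ntr)
    ep_sse <- 0
    for (s in seq(1, ntr, by = spec$batch_size)) {
      bi <- ord[s:min(s + spec$batch_size - 1, ntr)]
      xb <- xt[bi, , , drop = FALSE]
      fw <- net_forward(params, xb, spec, keep = TRUE)
      if (!all(is.finite(fw$pred)))
        stopf("network training diverged (non-finite loss) at epoch %d", ep)
      ep_sse <- ep_sse + sum((fw$pred - yt[bi])^2)
      grads <- net_backward(params, fw, yt[bi], spec)
      upd <- adam_step(params, grads, state, lr = spec$lr)
      params <- upd$params; state <- upd$state
    }
    monitor <- if (n_val > 0) net_loss(params, xv, yv, spec)
               else ep_sse / ntr
    history <- rbind(history, data.frame(epoch = ep, train_mse = ep_sse / ntr,
                                         val_mse = if (n_val > 0) monitor else NA))
    if (monitor < best$loss - 1e-9) {
      best <- list(loss = monitor, params = params)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= spec$patience) break
    }
  }
  new_trained_imputer(spec$family, best$params, norm, samples$predictors,
                      samples$exog_mode,
                      list(spec = spec, window = samples$window,
                           history = history))
}

# One-step prediction of normalized CO given a normalized input window
# (matrix window x channels, CO first) or lag feature vector.
predict_one <- function(model, window_block = NULL, lag_features = NULL) {
  if (model$family == "gbt") {
    X <- matrix(lag_features, 1, dimnames = list(NULL, model$features))
    return(predict(model$fit, xgboost::xgb.DMatrix(X)))
  }
  x <- array(window_block, c(1, nrow(window_block), ncol(window_block)))
  net_forward(model$fit, x, model$spec)$pred
}

#' Impute CO across one gap by recursive multi-step prediction
#'
#' Hours are imputed in chronological order; each prediction is fed back so
#' later hours use previously imputed CO in their lags or window (the only
#' scheme that can cross a 25-72 h gap when the CO lags fall inside it).
#' Exogenous channels are read from the series — inside artificial gaps
#' they were never masked; a missing exogenous cell is filled by
#' last-observation-carried-forward with a warning (or raises an error when
#' `exog_fallback = "error"`). Outputs are de-normalized to ppm. Hours
#' whose CO inputs included previously imputed values are flagged.
#'
#' @param model a `trained_imputer`.
#' @param series the `station_series` being imputed (normalized scale must
#'   match the model's training normalization; pass the raw series — it is
#'   normalized internally with the model's parameters).
#' @param gap one row of a `gap_intervals` data.frame (with `start_idx`,
#'   `end_idx`), or a list with those fields.
#' @param exog_fallback `"locf"` (default) or `"error"`.
#' @return data.frame of class `imputation_result`: `gap_id`, `model`,
#'   `timestamp`, `imputed_ppm`, `used_imputed_lags`.
#' @export
impute_gap <- function(model, series, gap, exog_fallback = c("locf", "error")) {
  exog_fallback <- match.arg(exog_fallback)
  s <- gap$start_idx[1]; e <- gap$end_idx[1]
  gid <- if (!is.null(gap$gap_id)) gap$gap_id[1] else NA_integer_
  L <- e - s + 1L
  if (L <= 0 || is.na(s))
    return(structure(data.frame(gap_id = integer(0), model = character(0),
                                timestamp = as.POSIXct(character(0), tz = "UTC"),
                                imputed_ppm = numeric(0),
                                used_imputed_lags = logical(0)),
                     class = c("imputation_result", "data.frame")))
  norm <- model$norm
  window <- if (model$family == "gbt") max(model$lags) else model$window
  if (s - window < 1) stopf("insufficient warm-up history before gap at row %d", s)

  # normalized working copies; CO gets imputations written into it
  co <- apply_normalizer(get_channel(series, "CO"), norm, "CO")
  if (anyNA(co[(s - window):(s - 1)]))
    stopf("warm-up window before the gap is not complete for CO")
  exog_vars <- model$predictors
  ex <- sapply(exog_vars, function(v)
    apply_normalizer(get_channel(series, v), norm, v))
  ex <- matrix(ex, ncol = length(exog_vars),
               dimnames = list(NULL, exog_vars))
  if (anyNA(ex[s:e, ])) {
    if (exog_fallback == "error")
      stopf("missing exogenous values inside the gap")
    warnf("missing exogenous values inside gap %s: filled by last observation carried forward", gid)
    for (j in seq_len(ncol(ex))) {
      v <- ex[, j]
      for (t in which(is.na(v))) if (t > 1) v[t] <- v[t - 1]
      ex[, j] <- v
    }
  }

  vals <- numeric(L)
  flags <- logical(L)
  for (k in seq_len(L)) {
    t <- s + k - 1L
    if (model$family == "gbt") {
      lag_idx <- t - model$lags
      flags[k] <- any(lag_idx >= s)
      feats <- c(co[lag_idx], ex[t, ])
      z <- predict_one(model, lag_features = feats)
    } else {
      flags[k] <- k > 1  # window overlaps the gap from the second hour on
      widx <- (t - window):(t - 1L)
      block <- cbind(CO = co[widx],
                     if (model$exog_mode == "window") ex[widx, , drop = FALSE]
                     else matrix(rep(ex[t, ], each = window), window,
                                 dimnames = list(NULL, exog_vars)))
      z <- predict_one(model, window_block = block)
    }
    co[t] <- z
    vals[k] <- invert_normalizer(z, norm, "CO")
  }
  structure(data.frame(gap_id = gid, model = model$family,
                       timestamp = series$time[s:e], imputed_ppm = vals,
                       used_imputed_lags = flags),
            class = c("imputation_result", "data.frame"))
}
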