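#' End-to-end run configuration
#'
#' One object drives the whole study: simulate (or load) the station,
#' census its gaps, inject artificial test gaps, build features, train the
#' three model families, impute every artificial gap, score the
#' imputations, and certify residual bias. Every stochastic stage derives
#' its own seed from `seed`.
#'
#' @param synthetic a `synthetic_config`, or `NULL` when `series_path`
#'   is given.
#' @param series_path path to a station CSV, or `NULL` when `synthetic`
#'   is given. Exactly one of the two must be provided.
#' @param plan an `injection_plan` (its `seed` is overridden by a derived
#'   seed).
#' @param models subset of `c("gbt", "lstm", "rnn")`.
#' @param net_predictors exogenous channels for the recurrent networks
#'   (default: the six contemporaneously correlated channels).
#' @param gbt_exog contemporaneous exogenous features of the tree model.
#' @param gbt_lags CO lags (hours) of the tree model.
#' @param gbt a `gbt_spec`.
#' @param net_epochs,net_batch_size,net_patience,net_max_train_samples
#'   recurrent-network training controls (see [net_spec()]).
#' @param exog_mode `"window"` or `"at_target"` (see [build_windows()]).
#' @param ccf_threshold predictor-screening threshold on `max |r|`,
#'   reported in the run output.
#' @param stats a `stats_config` (its `seed` is overridden).
#' @param seed master integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       series_path = NULL,
                       plan = injection_plan(),
                       models = c("gbt", "lstm", "rnn"),
                       net_predictors = c("NO2", "NO", "O3", "TEMP", "RH", "WS"),
                       gbt_exog = c("NO2", "NO", "TEMP", "RH"),
                       gbt_lags = c(12L, 24L, 36L, 48L),
                       gbt = gbt_spec(),
                       net_epochs = 30L, net_batch_size = 64L,
                       net_patience = 5L, net_max_train_samples = 4096L,
                       exog_mode = c("window", "at_target"),
                       ccf_threshold = 0.2,
                       stats = stats_config(),
                       seed = 1L) {
  if (is.null(synthetic) == is.null(series_path))
    stopf("provide exactly one of synthetic config or series_path")
  if (!is.null(series_path) && !file.exists(series_path))
    stopf("series file not found: %s", series_path)
  bad <- setdiff(models, c("gbt", "lstm", "rnn"))
  if (length(bad)) stopf("unknown model family: %s", bad[1])
  structure(list(synthetic = synthetic, series_path = series_path,
                 plan = plan, models = models,
                 net_predictors = net_predictors, gbt_exog = gbt_exog,
                 gbt_lags = gbt_lags, gbt = gbt,
                 net_epochs = as.integer(net_epochs),
                 net_batch_size = as.integer(net_batch_size),
                 net_patience = as.integer(net_patience),
                 net_max_train_samples = net_max_train_samples,
                 exog_mode = match.arg(exog_mode),
                 ccf_threshold = ccf_threshold, stats = stats,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `synthetic:` holds
#' [synthetic_config()] fields, `plan:` holds [injection_plan()] fields and
#' `stats:` the scalar fields of [stats_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$series_path)) {
    args$series_path <- y$series_path
    args$synthetic <- NULL
  } else if (!is.null(y$synthetic)) {
    args$synthetic <- do.call(synthetic_config, y$synthetic)
  }
  if (!is.null(y$plan)) args$plan <- do.call(injection_plan, y$plan)
  if (!is.null(y$stats)) args$stats <- do.call(stats_config, y$stats)
  if (!is.null(y$gbt)) args$gbt <- do.call(gbt_spec, y$gbt)
  for (k in c("models", "net_predictors", "gbt_exog", "gbt_lags",
              "net_epochs", "net_batch_size", "net_patience",
              "net_max_train_samples", "exog_mode", "ccf_threshold", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

pipeline_log <- function(log, stage, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(...))
  c(log, line)
}

#' Run the full imputation study
#'
#' Executes the stages in order: simulate/load -> gap census -> artificial
#' gap injection -> cross-correlation screening -> normalization and
#' sample construction -> model training -> recursive imputation of every
#' artificial gap -> accuracy metrics, distributional comparison and
#' confidence intervals -> residual-bias certification. Any stage failure
#' aborts with a stage-tagged error.
#'
#' @param config a `run_config`.
#' @return list of class `run_report` with the gap census, the
#'   artificial-gap manifest, per-gap scores for every model, metric
#'   distributions, Shapiro-Wilk and Kruskal-Wallis results, confidence
#'   intervals, accuracy-versus-horizon trends, per-gap bias test results
#'   and the unbiased-gap summary, plus a provenance block.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage %s failed: %s", name, conditionMessage(e)))
  }

  # -- data --------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- derive_seed(config$seed, 1L)
    complete <- stage("simulate", generate_station(syn))
    mech <- stage("simulate", inject_mechanism_gaps(complete, syn))
    series <- mech$series
    log <- pipeline_log(log, "simulate",
                        "seed=%d n_hours=%d mechanism_masked=%d",
                        syn$seed, n_hours(series), nrow(mech$truth))
  } else {
    series <- stage("load", read_station_csv(config$series_path))
    log <- pipeline_log(log, "load", "path=%s n_hours=%d",
                        config$series_path, n_hours(series))
  }

  # -- census of pre-existing gaps --------------------------------------
  gaps_real <- stage("census", find_gaps(series, "CO"))
  census <- stage("census", bin_gaps(gaps_real))
  log <- pipeline_log(log, "census", "n_real_gaps=%d", nrow(gaps_real))

  # -- artificial gaps ---------------------------------------------------
  plan <- config$plan
  plan$seed <- derive_seed(config$seed, 2L)
  gap_set <- stage("inject", inject_artificial_gaps(series, plan))
  test_series <- gap_set$series
  log <- pipeline_log(log, "inject", "n_gaps=%d masked_hours=%d",
                      nrow(gap_set$gaps), nrow(gap_set$truth))

  # -- predictor screening (reported; configured lists drive the models) -
  ccf <- stage("features", ccf_table(test_series))
  selected <- stage("features", select_predictors(ccf, config$ccf_threshold))
  log <- pipeline_log(log, "features", "ccf_selected=%s",
                      paste(selected, collapse = ","))

  # -- normalization and supervised samples ------------------------------
  all_vars <- unique(c("CO", config$net_predictors, config$gbt_exog))
  norm <- stage("features", fit_normalizer(test_series, all_vars))
  nser <- apply_normalizer(test_series, norm)
  windows <- stage("features",
                   build_windows(nser, config$net_predictors, 48L,
                                 exclusions = gap_set,
                                 exog_mode = config$exog_mode))
  lag_rows <- stage("features",
                    build_lag_rows(nser, exclusions = gap_set,
                                   lags = config$gbt_lags,
                                   exog = config$gbt_exog))
  log <- pipeline_log(log, "features", "n_windows=%d n_lag_rows=%d",
                      dim(windows$x)[1], nrow(lag_rows))

  # -- training ----------------------------------------------------------
  model_seeds <- c(gbt = 3L, lstm = 4L, rnn = 5L)
  trained <- list()
  for (fam in config$models) {
    sd_ <- derive_seed(config$seed, model_seeds[[fam]])
    trained[[fam]] <- stage(paste0("train_", fam),
      if (fam == "gbt") {
        train_gbt(lag_rows, config$gbt, norm = norm, seed = sd_)
      } else {
        spec <- net_spec(fam, epochs = config$net_epochs,
                         batch_size = config$net_batch_size,
                         patience = config$net_patience,
                         max_train_samples = config$net_max_train_samples,
                         seed = sd_)
        train_network(windows, spec, norm = norm)
      })
    log <- pipeline_log(log, paste0("train_", fam), "seed=%d", sd_)
  }

  # -- imputation, scoring and bias certification ------------------------
  scores <- list(); bias <- list(); imputations <- list()
  for (fam in config$models) {
    for (i in seq_len(nrow(gap_set$gaps))) {
      gap <- gap_set$gaps[i, ]
      imp <- stage("impute", impute_gap(trained[[fam]], test_series, gap))
      obs <- gap_set$truth$value[gap_set$truth$timestamp >= gap$start &
                                   gap_set$truth$timestamp <= gap$end]
      key <- paste(fam, gap$gap_id)
      imputations[[key]] <- imp
      scores[[key]] <- stage("evaluate",
                             score_gap(obs, imp$imputed_ppm,
                                       gap_id = gap$gap_id, model = fam))
      cfg_s <- config$stats
      cfg_s$seed <- derive_seed(config$seed, 6L)
      bias[[key]] <- stage("bias",
                           assess_gap_bias(obs - imp$imputed_ppm, cfg_s,
                                           gap_id = gap$gap_id, model = fam))
    }
  }
  scores <- if (length(scores)) do.call(rbind, scores) else NULL
  bias <- if (length(bias)) do.call(rbind, bias) else NULL
  if (!is.null(scores)) rownames(scores) <- rownames(bias) <- NULL
  log <- pipeline_log(log, "evaluate", "n_scores=%d",
                      if (is.null(scores)) 0L else nrow(scores))

  # -- distributional comparison ----------------------------------------
  has_scores <- !is.null(scores) && nrow(scores) > 2
  dist <- shapiro <- kw <- ci <- trend <- bias_summary <- NULL
  if (has_scores) {
    dist <- lapply(c(mae = "mae", rmse = "rmse", r2 = "r2"),
                   function(m) metric_distribution(scores, m))
    shapiro <- do.call(rbind, lapply(c("mae", "rmse", "r2"), function(m) {
      do.call(rbind, lapply(split(scores, scores$model), function(df) {
        v <- df[[m]][!is.na(df[[m]])]
        if (length(v) < 3) return(NULL)
        sw <- shapiro_wilk(v)
        data.frame(metric = m, model = df$model[1], W = sw$W, p = sw$p)
      }))
    }))
    rownames(shapiro) <- NULL
    kw <- do.call(rbind, lapply(c("mae", "rmse", "r2"), function(m) {
      groups <- lapply(split(scores, scores$model),
                       function(df) df[[m]][!is.na(df[[m]])])
      groups <- groups[vapply(groups, length, 0L) >= 1]
      if (length(groups) < 2) return(NULL)
      res <- kruskal_wallis(groups)
      data.frame(metric = m, H = res$H, df = res$df, p = res$p)
    }))
    ci <- do.call(rbind, lapply(c("mae", "rmse"), function(m) {
      do.call(rbind, lapply(split(scores, scores$model), function(df)
        cbind(model = df$model[1], mean_ci(df[[m]], metric = m))))
    }))
    rownames(ci) <- NULL
    trend <- fit_rmse_trend(scores)
    bias_summary <- summarize_bias(bias)
  }

  report <- list(census = census, real_gaps = gaps_real,
                 gap_manifest = gap_set$gaps, gap_set = gap_set,
                 ccf = ccf, selected_predictors = selected,
                 n_windows = dim(windows$x)[1], n_lag_rows = nrow(lag_rows),
                 trained = trained, imputations = imputations,
                 scores = scores, distributions = dist, shapiro = shapiro,
                 kruskal_wallis = kw, ci = ci, rmse_trend = trend,
                 bias = bias, bias_summary = bias_summary,
                 provenance = list(seed = config$seed,
                                   package_version = as.character(
                                     utils::packageVersion("cogapfill")),
                                   models = config$models,
                                   n_hours = n_hours(series),
                                   n_artificial_gaps = nrow(gap_set$gaps)),
                 log = log)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat(sprintf("  station hours: %d; artificial gaps: %d; windows: %d\n",
              x$provenance$n_hours, x$provenance$n_artificial_gaps,
              x$n_windows))
  if (!is.null(x$scores)) {
    cat("  median MAE / RMSE per model:\n")
    md <- metric_distribution(x$scores, "mae")
    rd <- metric_distribution(x$scores, "rmse")
    for (i in seq_len(nrow(md)))
      cat(sprintf("    %-5s %.4f / %.4f ppm\n", md$model[i], md$median[i],
                  rd$median[i]))
  }
  if (!is.null(x$bias_summary)) {
    cat("  unbiased gaps per model:\n")
    for (i in seq_len(nrow(x$bias_summary)))
      cat(sprintf("    %-5s %.1f%% (%d/%d)\n", x$bias_summary$model[i],
                  x$bias_summary$pct_unbiased[i],
                  x$bias_summary$n_unbiased[i], x$bias_summary$n_gaps[i]))
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Tables as delimited text, a machine-readable summary as JSON, and the
#' stage log as plain text. The directory is created if absent.
#'
#' @param report a `run_report`.
#' @param outdir output directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE, na = "")
    paths <<- c(paths, p)
  }
  wr(as.data.frame(report$census), "gap_census.csv")
  manifest <- report$gap_manifest
  if (!is.null(manifest)) {
    manifest$start <- format(manifest$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    manifest$end <- format(manifest$end, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    wr(manifest, "gap_manifest.csv")
  }
  if (!is.null(report$scores)) wr(report$scores, "scores.csv")
  if (!is.null(report$ci)) wr(report$ci, "confidence_intervals.csv")
  if (!is.null(report$bias)) wr(report$bias, "bias_tests.csv")
  if (!is.null(report$bias_summary)) wr(report$bias_summary, "bias_summary.csv")
  if (!is.null(report$rmse_trend)) wr(report$rmse_trend, "rmse_trend.csv")
  wr(report$ccf, "ccf_table.csv")

  summary <- list(provenance = report$provenance,
                  selected_predictors = report$selected_predictors,
                  n_windows = report$n_windows,
                  n_lag_rows = report$n_lag_rows,
                  kruskal_wallis = report$kruskal_wallis,
                  bias_summary = report$bias_summary)
  jp <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, jp)
  lp <- file.path(outdir, "run.log")
  writeLines(report$log, lp)
  invisible(c(paths, lp))
}
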