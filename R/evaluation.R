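#' Per-gap accuracy metrics
#'
#' `MAE = mean|o - p|`, `RMSE = sqrt(mean (o - p)^2)`,
#' `R2 = 1 - SSE / SST` where the baseline is the within-gap observed mean
#' — so `R2` can be negative, and is `NA` (reported as undefined) when the
#' observed values have zero variance inside the gap.
#'
#' @param observed ground-truth ppm sequence.
#' @param imputed imputed ppm sequence, same length (>= 2).
#' @param gap_id,model identifiers carried into the result.
#' @return one-row data.frame of class `gap_score`: `gap_id`, `model`,
#'   `duration_h`, `mae`, `rmse`, `r2`.
#' @export
score_gap <- function(observed, imputed, gap_id = NA_integer_,
                      model = NA_character_) {
  if (length(observed) != length(imputed))
    stopf("observed and imputed must have equal length")
  if (length(observed) < 2) stopf("need at least 2 values to score a gap")
  err <- observed - imputed
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(err^2) / sst
  structure(data.frame(gap_id = gap_id, model = model,
                       duration_h = length(observed),
                       mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
                       r2 = r2),
            class = c("gap_score", "data.frame"))
}

#' Distribution summary of a metric per model
#'
#' Median and quartiles use the linear-interpolation convention of
#' [stats::quantile()] type 7; whiskers extend to the most extreme values
#' within 1.5 IQR of the quartiles (the usual boxplot convention).
#'
#' @param scores a data.frame of `gap_score` rows.
#' @param metric `"mae"`, `"rmse"` or `"r2"`.
#' @return data.frame with one row per model: `model`, `n`, `median`,
#'   `q1`, `q3`, `whisker_lo`, `whisker_hi`.
#' @export
metric_distribution <- function(scores, metric = c("mae", "rmse", "r2")) {
  metric <- match.arg(metric)
  rows <- lapply(split(scores, scores$model), function(df) {
    v <- df[[metric]]
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(model = df$model[1], n = length(v), median = q[2],
               q1 = q[1], q3 = q[3],
               whisker_lo = min(v[v >= q[1] - 1.5 * iqr]),
               whisker_hi = max(v[v <= q[3] + 1.5 * iqr]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] (3 <= n <= 5000).
#'
#' @param values numeric sample.
#' @return list `(W, p)`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000)
    stopf("Shapiro-Wilk requires 3 <= n <= 5000")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Kruskal-Wallis comparison of model metric distributions
#'
#' Rank-based omnibus test with tie correction; p-value from the
#' chi-square distribution with k - 1 degrees of freedom.
#'
#' @param groups named list of numeric vectors (one per model).
#' @return list of class `kw_result`: `H`, `df`, `p`, `group_sizes`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  sizes <- vapply(groups, length, 0L)
  if (any(sizes < 1) || sum(sizes) < 5)
    stopf("each group needs n >= 1 and total n >= 5")
  ht <- stats::kruskal.test(unlist(groups, use.names = FALSE),
                            factor(rep(seq_along(groups), sizes)))
  structure(list(H = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, group_sizes = sizes),
            class = "kw_result")
}

#' Confidence interval for the mean of a metric
#'
#' Student-t interval `mean +/- t_{1-(1-level)/2, n-1} * s / sqrt(n)` by
#' default; a normal-quantile interval is available via `method = "z"`.
#'
#' @param values numeric sample (n >= 2).
#' @param level confidence level (default 0.95).
#' @param method `"t"` (default) or `"z"`.
#' @param metric label carried into the result.
#' @return one-row data.frame of class `ci_result`: `metric`, `n`, `mean`,
#'   `lower`, `upper`, `half_width`, `level`.
#' @export
mean_ci <- function(values, level = 0.95, method = c("t", "z"),
                    metric = NA_character_) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stopf("need n >= 2 for a confidence interval")
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  q <- if (method == "t") stats::qt(1 - (1 - level) / 2, n - 1)
       else stats::qnorm(1 - (1 - level) / 2)
  structure(data.frame(metric = metric, n = n, mean = m,
                       lower = m - q * se, upper = m + q * se,
                       half_width = q * se, level = level),
            class = c("ci_result", "data.frame"))
}

#' Linear trend of RMSE against gap duration
#'
#' Ordinary least squares of per-gap RMSE on gap duration (hours), one fit
#' per model — the accuracy-versus-horizon trend.
#'
#' @param scores a data.frame of `gap_score` rows.
#' @return data.frame with columns `model`, `slope`, `intercept`, `n`.
#' @export
fit_rmse_trend <- function(scores) {
  rows <- lapply(split(scores, scores$model), function(df) {
    if (length(unique(df$duration_h)) < 2)
      stopf("need >= 2 distinct durations for a trend fit")
    co <- stats::coef(stats::lm(rmse ~ duration_h, data = df))
    data.frame(model = df$model[1], slope = unname(co[2]),
               intercept = unname(co[1]), n = nrow(df))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
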