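#' Plan for injecting artificial test gaps
#'
#' Artificial gaps are contiguous runs masked out of the target channel in
#' regions where the series is complete, so that imputations can be scored
#' against held-out truth. Lengths are integer hours drawn uniformly from
#' `[min_len, max_len]` (default 25-72 h, the medium-gap validation range);
#' gaps are pairwise disjoint, never overlap pre-existing gaps, and each is
#' preceded by a buffer of 48 fully observed hours so every imputer has a
#' complete warm-up window.
#'
#' @param n_gaps number of gaps to place (the reference benchmark uses 46).
#' @param min_len,max_len inclusive integer bounds on gap length (hours).
#' @param target_variable channel to mask (default `"CO"`).
#' @param require_complete_exog if `TRUE` (default), a placement is feasible
#'   only where every channel — not just the target — is observed across the
#'   buffer and the gap itself.
#' @param buffer_h complete warm-up hours required before each gap.
#' @param seed integer seed for lengths and placements.
#' @param max_retries rejected placements allowed before giving up.
#' @return A list of class `injection_plan`.
#' @export
injection_plan <- function(n_gaps = 46L, min_len = 25L, max_len = 72L,
                           target_variable = "CO",
                           require_complete_exog = TRUE,
                           buffer_h = 48L, seed = 1L, max_retries = 1000L) {
  if (!is_count(n_gaps)) stopf("n_gaps must be a nonnegative integer")
  if (min_len < 1 || min_len > max_len)
    stopf("need 1 <= min_len <= max_len")
  structure(list(n_gaps = as.integer(n_gaps), min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 target_variable = target_variable,
                 require_complete_exog = isTRUE(require_complete_exog),
                 buffer_h = as.integer(buffer_h), seed = as.integer(seed),
                 max_retries = as.integer(max_retries)),
            class = "injection_plan")
}

#' Inject artificial test gaps into a station series
#'
#' Sequential rejection sampling: for each gap a length is drawn uniformly
#' on `[min_len, max_len]` and a start hour uniformly among all placements
#' that keep the gap (plus its preceding warm-up buffer) inside a region
#' where the required channels are observed and that avoid every
#' pre-existing and previously placed gap. Masked values are kept as ground
#' truth; masked cells are tagged `"artificial-gap"`.
#'
#' @param series a `station_series` with contiguous hourly timestamps.
#' @param plan an `injection_plan`.
#' @return list of class `artificial_gap_set`: `series` (masked),
#'   `gaps` (`gap_intervals` with a `gap_id` column), `truth` (ground-truth
#'   rows for the masked cells) and `plan`.
#' @export
inject_artificial_gaps <- function(series, plan) {
  stopifnot(inherits(plan, "injection_plan"))
  local_rng()
  n <- n_hours(series)
  tv <- plan$target_variable
  target <- get_channel(series, tv)

  req <- if (plan$require_complete_exog) STATION_CHANNELS else tv
  ok <- !Reduce(`|`, lapply(req, function(ch) is.na(get_channel(series, ch))))
  avail <- ok # shrinks as gaps are placed

  if (plan$n_gaps == 0) {
    out <- list(series = series,
                gaps = cbind(gap_id = integer(0),
                             gaps_from_mask(logical(n), series$time, tv)[0, ]),
                truth = empty_ground_truth(), plan = plan)
    class(out) <- "artificial_gap_set"
    return(out)
  }

  set.seed(plan$seed)
  b <- plan$buffer_h
  placed <- list()
  retries <- 0L
  while (length(placed) < plan$n_gaps) {
    len <- plan$min_len + floor(runif(1) * (plan$max_len - plan$min_len + 1))
    # feasible starts s: window [s - b, s + len - 1] entirely available
    w <- b + len
    cs <- c(0, cumsum(avail))
    first <- b + 1L
    last <- n - len + 1L
    feas <- if (last >= first) {
      s_cand <- first:last
      s_cand[cs[s_cand + len] - cs[s_cand - b] == w]
    } else integer(0)
    if (!length(feas)) {
      retries <- retries + 1L
      if (retries > plan$max_retries)
        stopf("artificial gap placement infeasible: placed %d of %d gaps",
              length(placed), plan$n_gaps)
      next
    }
    s <- feas[sample.int(length(feas), 1L)]
    e <- s + len - 1L
    # reserve the warm-up buffer too, so no later gap can invade it
    # (keeps every placed gap's 48 preceding hours observed, and makes
    # adjacent runs that would merge into one longer gap impossible)
    avail[(s - b):e] <- FALSE
    placed[[length(placed) + 1L]] <- c(s, e)
  }

  placed <- placed[order(vapply(placed, `[`, 0, 1))]
  mask <- logical(n)
  for (g in placed) mask[g[1]:g[2]] <- TRUE

  gaps <- gaps_from_mask(mask, series$time, tv)
  gaps <- cbind(gap_id = seq_len(nrow(gaps)), gaps)

  truth <- data.frame(variable = tv, timestamp = series$time[mask],
                      value = target[mask])
  data <- series$data
  data[[tv]][mask] <- NA_real_
  prov <- series$provenance
  prov[mask, tv] <- "artificial-gap"

  out <- list(series = station_series(series$time, data, prov),
              gaps = gaps, truth = truth, plan = plan)
  class(out) <- "artificial_gap_set"
  out
}

#' @export
print.artificial_gap_set <- function(x, ...) {
  cat(sprintf("artificial_gap_set: %d gaps on %s, durations %d-%d h, %d masked hours\n",
              nrow(x$gaps), x$plan$target_variable,
              if (nrow(x$gaps)) min(x$gaps$duration_h) else 0L,
              if (nrow(x$gaps)) max(x$gaps$duration_h) else 0L,
              nrow(x$truth)))
  invisible(x)
}

#' Write an artificial gap manifest as delimited text
#' @param gap_set an `artificial_gap_set`.
#' @param path file path for the manifest (`gap_id,start,end,duration_h`).
#' @export
write_gap_manifest_csv <- function(gap_set, path) {
  df <- data.frame(gap_id = gap_set$gaps$gap_id,
                   start = format(gap_set$gaps$start, "%Y-%m-%dT%H:%M:%S",
                                  tz = "UTC"),
                   end = format(gap_set$gaps$end, "%Y-%m-%dT%H:%M:%S",
                                tz = "UTC"),
                   duration_h = gap_set$gaps$duration_h)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
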