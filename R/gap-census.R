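#' Detect contiguous missing runs in one channel
#'
#' A gap is a maximal run of consecutive missing hours. Runs touching the
#' series boundary are reported with their observed (truncated) duration.
#'
#' @param series a `station_series`.
#' @param variable channel name.
#' @return data.frame of class `gap_intervals` with columns `variable`,
#'   `start`, `end` (timestamps of the first and last missing hour),
#'   `start_idx`, `end_idx` (1-based row indices) and `duration_h`; sorted
#'   by `start`. A complete channel yields zero rows.
#' @export
find_gaps <- function(series, variable) {
  x <- get_channel(series, variable)
  miss <- is.na(x)
  gaps_from_mask(miss, series$time, variable)
}

# Shared run-length core: maximal TRUE runs of a logical mask.
gaps_from_mask <- function(miss, timestamps, variable) {
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(
    variable = rep(variable, sum(keep)),
    start = timestamps[starts[keep]],
    end = timestamps[ends[keep]],
    start_idx = starts[keep],
    end_idx = ends[keep],
    duration_h = r$lengths[keep]
  )
  rownames(out) <- NULL
  class(out) <- c("gap_intervals", "data.frame")
  out
}

#' Summarize gaps in the four standard duration bins
#'
#' Bins: short (1-24 h), medium (25-72 h), long (73-120 h), very long
#' (121-168 h); durations above 168 h fall into an overflow bin. Empty bins
#' report mean and max duration 0.0 by convention.
#'
#' @param gaps a `gap_intervals` data.frame (or anything with a
#'   `duration_h` column).
#' @return data.frame of class `gap_census` with columns `label`,
#'   `range_lo`, `range_hi`, `n_gaps`, `mean_duration_h`, `max_duration_h`.
#' @export
bin_gaps <- function(gaps) {
  d <- gaps$duration_h
  if (length(d) && any(d < 1)) stopf("gap durations must be >= 1")
  bins <- rbind(GAP_BINS, data.frame(label = "overflow", lo = 169, hi = Inf))
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    sel <- d >= bins$lo[i] & d <= bins$hi[i]
    data.frame(label = bins$label[i], range_lo = bins$lo[i],
               range_hi = bins$hi[i], n_gaps = sum(sel),
               mean_duration_h = if (any(sel)) mean(d[sel]) else 0,
               max_duration_h = if (any(sel)) max(d[sel]) else 0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gap_census", "data.frame")
  out
}

#' Write a gap census as delimited text
#' @param census a `gap_census`.
#' @param path file path.
#' @export
write_gap_census_csv <- function(census, path) {
  utils::write.csv(as.data.frame(census), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
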