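#' Hourly multivariate station series
#'
#' The exchange object used by every stage of the pipeline: a strictly
#' hourly, contiguous time axis and ten named channels (`CO`, `NO`, `NO2`,
#' `NOX`, `O3`, `SO2`, `PM`, `TEMP`, `RH`, `WS`), each a numeric vector in
#' which `NA` marks a missing hour. A per-cell provenance tag records whether
#' a cell is observed, missing through the simulated station mechanism, or
#' masked as an artificial test gap.
#'
#' @param timestamps `POSIXct` vector, strictly increasing with a 1 h step.
#' @param data data.frame with one numeric column per channel; all columns
#'   the same length as `timestamps`. Missing channels are added as all-`NA`.
#' @param provenance optional character matrix (`length(timestamps)` x
#'   channels) with entries `"observed"`, `"mechanism-gap"` or
#'   `"artificial-gap"`. Defaults to `"observed"` where a value is present
#'   and `"mechanism-gap"` where it is `NA`.
#'
#' @return An object of class `station_series`.
#' @export
station_series <- function(timestamps, data, provenance = NULL) {
  if (!inherits(timestamps, "POSIXct"))
    stopf("timestamps must be POSIXct")
  n <- length(timestamps)
  if (n >= 2) {
    steps <- as.double(diff(as.numeric(timestamps)))
    if (any(steps != 3600))
      stopf("timestamps must be strictly increasing with a 1 h step")
  }
  data <- as.data.frame(data)
  missing_ch <- setdiff(STATION_CHANNELS, names(data))
  for (ch in missing_ch) data[[ch]] <- rep(NA_real_, n)
  data <- data[STATION_CHANNELS]
  for (ch in STATION_CHANNELS) {
    if (!is.numeric(data[[ch]]))
      stopf("channel %s must be numeric", ch)
    if (length(data[[ch]]) != n)
      stopf("channel %s has length %d, expected %d", ch, length(data[[ch]]), n)
  }
  if (is.null(provenance)) {
    provenance <- matrix("observed", n, length(STATION_CHANNELS),
                         dimnames = list(NULL, STATION_CHANNELS))
    provenance[is.na(as.matrix(data))] <- "mechanism-gap"
  } else {
    provenance <- as.matrix(provenance)
    if (!all(dim(provenance) == c(n, length(STATION_CHANNELS))))
      stopf("provenance must be a %d x %d matrix", n, length(STATION_CHANNELS))
    colnames(provenance) <- STATION_CHANNELS
    bad <- setdiff(unique(as.vector(provenance)),
                   c("observed", "mechanism-gap", "artificial-gap"))
    if (length(bad)) stopf("unknown provenance tag: %s", bad[1])
  }
  structure(list(time = timestamps, data = data, provenance = provenance),
            class = "station_series")
}

#' @export
print.station_series <- function(x, ...) {
  n <- length(x$time)
  miss <- vapply(x$data, function(v) sum(is.na(v)), 0L)
  cat(sprintf("station_series: %d hourly observations (%s .. %s)\n", n,
              format(x$time[1], "%Y-%m-%d %H:%M", tz = "UTC"),
              format(x$time[n], "%Y-%m-%d %H:%M", tz = "UTC")))
  cat("missing cells per channel:\n")
  print(miss)
  invisible(x)
}

#' Number of hours in a station series
#' @param series a `station_series`.
#' @return integer count of hourly rows.
#' @export
n_hours <- function(series) length(series$time)

#' Channel names of a station series
#' @param series a `station_series`.
#' @return character vector of channel names.
#' @export
station_channels <- function(series) names(series$data)

#' Extract one channel as a numeric vector
#' @param series a `station_series`.
#' @param variable channel name.
#' @return numeric vector (`NA` = missing).
#' @export
get_channel <- function(series, variable) {
  if (!variable %in% names(series$data))
    stopf("unknown variable: %s", variable)
  series$data[[variable]]
}

#' Write / read a station series as delimited text
#'
#' Comma-separated with header `timestamp,CO,NO,...,WS`; timestamps ISO-8601
#' (UTC); missing cells empty. Provenance is not persisted: on read, missing
#' cells are tagged `"mechanism-gap"`.
#'
#' @param series a `station_series`.
#' @param path file path.
#' @return `write_station_csv` returns `path` invisibly; `read_station_csv`
#'   returns a `station_series`.
#' @export
write_station_csv <- function(series, path) {
  df <- data.frame(timestamp = format(series$time, "%Y-%m-%dT%H:%M:%S",
                                      tz = "UTC"),
                   series$data, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_station_csv
#' @export
read_station_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (names(df)[1] != "timestamp") stopf("first column must be 'timestamp'")
  tt <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(tt)) stopf("unparseable ISO-8601 timestamps in %s", path)
  for (ch in setdiff(names(df), "timestamp")) df[[ch]] <- as.numeric(df[[ch]])
  station_series(tt, df[setdiff(names(df), "timestamp")])
}

#' Write / read held-out ground truth for masked cells
#'
#' Ground truth is a data.frame `variable, timestamp, value` covering exactly
#' the cells that were turned missing by a masking step.
#'
#' @param truth ground-truth data.frame.
#' @param path file path.
#' @return `read_ground_truth_csv` returns the data.frame.
#' @export
write_ground_truth_csv <- function(truth, path) {
  out <- data.frame(variable = truth$variable,
                    timestamp = format(truth$timestamp, "%Y-%m-%dT%H:%M:%S",
                                       tz = "UTC"),
                    value = truth$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth_csv
#' @export
read_ground_truth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
  df
}

# Empty ground-truth table with the canonical columns.
empty_ground_truth <- function() {
  data.frame(variable = character(0),
             timestamp = as.POSIXct(character(0), tz = "UTC"),
             value = numeric(0))
}
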