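#' Read a spike table (channel, time) from TSV or CSV
#'
#' Expects a header with columns `channel` and `time_ms`; the delimiter
#' (tab or comma) is auto-detected.  Times are sorted on read; unknown
#' extra columns produce a warning and are dropped.
#'
#' @param path input file
#' @return data frame with integer `channel` and numeric `time_ms`, sorted
#'   by time
#' @export
read_spike_table <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("channel", "time_ms") %in% names(df)))
    stop("read_spike_table: need columns 'channel' and 'time_ms' in ", path)
  extra <- setdiff(names(df), c("channel", "time_ms"))
  if (length(extra))
    warning("read_spike_table: ignoring unknown columns: ",
            paste(extra, collapse = ", "))
  df <- df[, c("channel", "time_ms")]
  bad <- which(!is.finite(df$time_ms) | df$time_ms < 0 |
                 df$channel != round(df$channel) | df$channel < 0)
  if (length(bad))
    stop("read_spike_table: malformed row(s) at line(s) ",
         paste(head(bad + 1L, 5), collapse = ", "))
  df$channel <- as.integer(df$channel)
  df[order(df$time_ms), , drop = FALSE]
}

#' Write a spike table as TSV
#'
#' @param spikes data frame with `channel` and `time_ms`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_spike_table <- function(spikes, path) {
  stopifnot(all(c("channel", "time_ms") %in% names(spikes)))
  write.table(spikes[, c("channel", "time_ms")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a count series as TSV (`bin_index`, `count`)
#'
#' @param series a [count_series()]
#' @param path file path
#' @return `path` / a [count_series()]
#' @export
write_count_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_bin_ms=%g t0_ms=%g", series$dt_bin, series$t0),
             con)
  write.table(data.frame(bin_index = seq_along(series$counts) - 1L,
                         count = series$counts),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_series
#' @export
read_count_series <- function(path) {
  meta <- readLines(path, n = 1)
  dt_bin <- as.numeric(sub(".*dt_bin_ms=([0-9.eE+-]+).*", "\\1", meta))
  t0 <- as.numeric(sub(".*t0_ms=([0-9.eE+-]+).*", "\\1", meta))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  count_series(df$count, dt_bin, t0)
}

#' Write detected events as TSV plus a JSON sidecar
#'
#' The TSV carries one row per event (`onset_ms`, `offset_ms`,
#' `duration_ms`, `size`, `peak`, `label`); the sidecar
#' (`<path>.json`) records the fitted HMM parameters, the duration
#' threshold and the detector configuration for provenance.
#'
#' @param events an `event_list` from [detect_events()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_events <- function(events, path) {
  df <- data.frame(onset_ms = events$onset_ms,
                   offset_ms = events$onset_ms + events$duration_ms,
                   duration_ms = events$duration_ms,
                   size = events$size, peak = events$peak,
                   label = events$label)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  hmm <- attr(events, "hmm")
  cfg <- attr(events, "config")
  side <- list(dt_bin = attr(events, "dt_bin"),
               threshold_ms = attr(events, "threshold_ms"),
               hmm = if (!is.null(hmm))
                 list(lambda = hmm$lambda, trans = as.vector(hmm$trans),
                      init = hmm$init, clamp = hmm$clamp, p1 = hmm$p1),
               config = if (!is.null(cfg)) unclass(cfg))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an events TSV written by [write_events()]
#'
#' @param path TSV path
#' @param dt_bin bin width (ms) used to reconstruct bin indices
#' @return an `event_list` data frame
#' @export
read_events <- function(path, dt_bin = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (is.null(dt_bin)) {
    side <- paste0(path, ".json")
    if (file.exists(side))
      dt_bin <- jsonlite::read_json(side)$dt_bin
  }
  if (is.null(dt_bin)) stop("read_events: dt_bin unknown")
  ev <- data.frame(onset_bin = as.integer(round(df$onset_ms / dt_bin)),
                   offset_bin = as.integer(round(df$offset_ms / dt_bin)),
                   onset_ms = df$onset_ms, duration_ms = df$duration_ms,
                   size = df$size, peak = df$peak, label = df$label)
  structure(ev, class = c("event_list", "data.frame"), dt_bin = dt_bin)
}
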