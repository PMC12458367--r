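#' Per-cisterna fluorescence trace
#'
#' Time series of background-subtracted intensities for one maturing Golgi
#' cisterna, one column per fluorescence channel. Times must be strictly
#' increasing and uniformly spaced (tracking software emits fixed-interval
#' volumetric frames, 2 s by default).
#'
#' @param times numeric vector of acquisition times, s.
#' @param channels named list of numeric vectors (one per channel, same length
#'   as `times`) or a named matrix/data.frame.
#' @param cisterna_id identifier.
#' @param condition condition label (e.g. `"control"`, `"rapamycin"`).
#' @param background optional named numeric vector of per-channel background
#'   estimates.
#' @return object of class `cisterna_trace`: list with `times`, `channels`
#'   (named list), `cisterna_id`, `condition`, `background`.
#' @export
cisterna_trace <- function(times, channels, cisterna_id = NA_character_,
                           condition = NA_character_, background = NULL) {
  if (is.matrix(channels) || is.data.frame(channels))
    channels <- as.list(as.data.frame(channels))
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("`channels` must be named")
  n <- length(times)
  if (n < 2) stop("a trace needs at least two timepoints")
  dt <- diff(times)
  if (any(dt <= 0)) stop("`times` must be strictly increasing")
  if (max(dt) - min(dt) > 1e-8 * max(dt)) stop("`times` must be uniformly spaced")
  for (ch in names(channels)) {
    if (length(channels[[ch]]) != n)
      stop(sprintf("channel `%s` length differs from `times`", ch))
    if (any(!is.finite(channels[[ch]])))
      stop(sprintf("channel `%s` has non-finite values", ch))
  }
  structure(
    list(times = as.numeric(times), channels = lapply(channels, as.numeric),
         cisterna_id = cisterna_id, condition = condition,
         background = background),
    class = "cisterna_trace"
  )
}

#' @export
print.cisterna_trace <- function(x, ...) {
  cat(sprintf("<cisterna_trace> %s: %d frames (%g s interval), channels: %s\n",
              x$cisterna_id, length(x$times), diff(x$times[1:2]),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

trace_interval <- function(trace) diff(trace$times[1:2])

# apply f(values, ...) to one channel or every channel of a trace
map_channels <- function(trace, f, ...) {
  trace$channels <- lapply(trace$channels, f, ...)
  trace
}

#' Read and write trace tables
#'
#' Long-to-wide CSV interchange: columns `cisterna_id`, `time_s`, one column
#' per channel (`ch_<name>`), and `condition`.
#'
#' @param traces list of [cisterna_trace()] objects.
#' @param path CSV path.
#' @return `write_traces_csv()` the path, invisibly; `read_traces_csv()` a
#'   list of [cisterna_trace()].
#' @export
write_traces_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    df <- data.frame(cisterna_id = tr$cisterna_id, time_s = tr$times,
                     check.names = FALSE)
    for (ch in names(tr$channels)) df[[paste0("ch_", ch)]] <- tr$channels[[ch]]
    df$condition <- tr$condition
    df
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  ch_cols <- grep("^ch_", names(df), value = TRUE)
  lapply(split(df, df$cisterna_id), function(d) {
    d <- d[order(d$time_s), ]
    chans <- lapply(ch_cols, function(cc) d[[cc]])
    names(chans) <- sub("^ch_", "", ch_cols)
    cisterna_trace(d$time_s, chans, cisterna_id = d$cisterna_id[1],
                   condition = d$condition[1])
  })
}
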