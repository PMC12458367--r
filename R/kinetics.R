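#' Correct a trace for photobleaching
#'
#' Fits a single-exponential decay to a whole-cell (or ensemble) reference
#' series by least squares on the log signal and divides every channel by
#' `g(t) / g(0)`, so the first timepoint is unchanged. Channel ratios at each
#' timepoint are preserved because the divisor is a scalar per timepoint.
#'
#' @param trace a [cisterna_trace()].
#' @param reference numeric series to fit the decay to (same length as the
#'   trace); defaults to the sum of all channels, a proxy for total cellular
#'   signal.
#' @return corrected [cisterna_trace()] with attribute `bleach_rate` (1/s).
#' @export
bleach_correct <- function(trace, reference = NULL) {
  stopifnot(inherits(trace, "cisterna_trace"))
  t <- trace$times
  if (length(t) < 5) stop("need at least 5 timepoints to fit bleaching")
  ref <- reference %||% Reduce(`+`, trace$channels)
  if (length(ref) != length(t)) stop("`reference` length mismatch")
  pos <- is.finite(ref) & ref > 0
  if (sum(pos) < 5) stop("cannot fit bleaching: fewer than 5 positive reference points")
  fit <- lm(log(ref[pos]) ~ t[pos])
  rate <- -unname(coef(fit)[2])
  g <- exp(-rate * (t - t[1]))
  if (any(!is.finite(g)) || any(g <= 0))
    stop("non-positive fitted decay")
  out <- map_channels(trace, function(v) v / g)
  attr(out, "bleach_rate") <- rate
  out
}

#' Smooth a trace with a boxcar window
#'
#' Moving average of odd width `window`; endpoints use shrinking windows so
#' the output has the trace's length. `window = 1` is the identity.
#'
#' @param trace a [cisterna_trace()] (all channels smoothed) or numeric
#'   vector.
#' @param window odd integer window width, in frames.
#' @return same type as the input.
#' @export
smooth_trace <- function(trace, window = 3) {
  if (window < 1 || window %% 2 == 0) stop("`window` must be odd and >= 1")
  n <- if (inherits(trace, "cisterna_trace")) length(trace$times) else length(trace)
  if (window > n) stop("`window` exceeds trace length")
  if (inherits(trace, "cisterna_trace")) map_channels(trace, boxcar, window = window)
  else boxcar(trace, window)
}

#' Normalize a trace to the unit interval
#'
#' Subtracts a baseline (the 10th percentile of frames preceding the first
#' provisional detection, i.e. the first frame above 20% of the dynamic
#' range; the minimum if no such pre-arrival frames exist) and divides by the
#' resulting maximum, then clips to `[0, 1]`. The result has maximum exactly
#' 1 and baseline approximately 0; the operation is idempotent and invariant
#' under positive affine transforms of the input.
#'
#' @param trace a [cisterna_trace()] (each channel normalized independently)
#'   or numeric vector.
#' @param baseline_quantile quantile of the pre-arrival frames used as
#'   baseline.
#' @return same type as the input, values in `[0, 1]`.
#' @examples
#' normalize_trace(c(10, 10, 40, 70, 10))
#' @export
normalize_trace <- function(trace, baseline_quantile = 0.1) {
  if (inherits(trace, "cisterna_trace"))
    return(map_channels(trace, normalize_trace, baseline_quantile = baseline_quantile))
  x <- as.numeric(trace)
  rng <- range(x)
  if (diff(rng) <= 0) stop("no dynamic range: trace is flat")
  provisional <- rng[1] + 0.2 * diff(rng)
  first_up <- which(x > provisional)[1]
  # type-1 (order-statistic) quantile: affine-equivariant and exactly
  # idempotent after the [0, 1] clip
  baseline <- if (!is.na(first_up) && first_up > 1)
    unname(quantile(x[seq_len(first_up - 1L)], baseline_quantile, type = 1))
  else rng[1]
  denom <- max(x) - baseline
  if (denom <= 0) stop("no dynamic range: baseline equals maximum")
  pmin(1, pmax(0, (x - baseline) / denom))
}

# First upward crossing of `level`, linearly interpolated; NA if none.
first_upward_crossing <- function(times, values, level = 0.5) {
  idx <- which(values[-1] >= level & values[-length(values)] < level)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  times[i] + (level - values[i]) / (values[i + 1] - values[i]) *
    (times[i + 1] - times[i])
}

#' Align traces at a kinetic landmark and average them
#'
#' Each trace is time-shifted so that the first upward half-maximum crossing
#' of its normalized reference channel sits at t = 0, every channel is
#' normalized to `[0, 1]`, and per-timepoint means, SDs and contributing
#' counts are computed on a common grid at the traces' frame interval.
#' Traces whose reference channel never crosses 0.5 upward are excluded with
#' a warning.
#'
#' @param traces list of [cisterna_trace()] objects sharing a frame interval
#'   and channel set.
#' @param reference_channel channel used for the alignment landmark.
#' @param level landmark level on the normalized reference channel.
#' @return tibble of class `aligned_average` with columns `time` (s, 0 at the
#'   landmark), `channel`, `mean`, `sd`, `n`; attribute `landmarks` holds the
#'   per-trace landmark times on the original time axes.
#' @export
align_traces <- function(traces, reference_channel, level = 0.5) {
  if (length(traces) < 2) stop("need at least 2 traces to average")
  dt <- trace_interval(traces[[1]])
  norm_traces <- list(); landmarks <- numeric(0)
  for (tr in traces) {
    stopifnot(inherits(tr, "cisterna_trace"))
    if (abs(trace_interval(tr) - dt) > 1e-9) stop("traces differ in frame interval")
    if (!reference_channel %in% names(tr$channels))
      stop(sprintf("trace %s lacks reference channel '%s'", tr$cisterna_id,
                   reference_channel))
    ref <- normalize_trace(tr$channels[[reference_channel]])
    t0 <- first_upward_crossing(tr$times, ref, level)
    if (is.na(t0)) {
      warning(sprintf("trace %s has no upward %.2f crossing on '%s'; excluded",
                      tr$cisterna_id, level, reference_channel))
      next
    }
    ntr <- map_channels(tr, normalize_trace)
    ntr$times <- tr$times - t0
    norm_traces[[length(norm_traces) + 1L]] <- ntr
    landmarks <- c(landmarks, t0)
  }
  if (length(norm_traces) < 2) stop("fewer than 2 alignable traces")

  starts <- vapply(norm_traces, function(x) x$times[1], numeric(1))
  ends <- vapply(norm_traces, function(x) tail(x$times, 1), numeric(1))
  grid <- seq(-ceiling(-min(starts) / dt), ceiling(max(ends) / dt)) * dt
  grid <- grid[grid >= min(starts) & grid <= max(ends)]

  channels <- names(norm_traces[[1]]$channels)
  out <- list()
  for (ch in channels) {
    vals <- sapply(norm_traces, function(tr) {
      inside <- grid >= tr$times[1] & grid <= tail(tr$times, 1)
      v <- rep(NA_real_, length(grid))
      v[inside] <- approx(tr$times, tr$channels[[ch]], xout = grid[inside])$y
      v
    })
    vals <- matrix(vals, nrow = length(grid))
    n <- rowSums(!is.na(vals))
    keep <- n >= 1
    out[[ch]] <- tibble::tibble(
      time = grid[keep], channel = ch,
      mean = rowMeans(vals, na.rm = TRUE)[keep],
      sd = apply(vals, 1, sd, na.rm = TRUE)[keep],
      n = n[keep]
    )
  }
  res <- do.call(rbind, out)
  attr(res, "landmarks") <- landmarks
  class(res) <- c("aligned_average", class(res))
  res
}

# Threshold detection of the visible interval of one channel.
# Returns interpolated first/last times where the signal exceeds
# background + k * SD for >= m consecutive frames.
detect_visible <- function(times, values, k = 3, m = 2,
                           background = NULL, noise_sd = NULL) {
  bg <- background %||% unname(quantile(values, 0.25))
  noise <- noise_sd %||% (mad(diff(values)) / sqrt(2))
  thr <- bg + k * noise
  above <- values > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= m)
  if (!length(ok))
    return(list(detected = FALSE, first = NA_real_, last = NA_real_,
                threshold = thr))
  i1 <- starts[ok[1]]; i2 <- ends[ok[length(ok)]]
  n <- length(values)
  first <- if (i1 > 1)
    times[i1 - 1] + (thr - values[i1 - 1]) / (values[i1] - values[i1 - 1]) *
      (times[i1] - times[i1 - 1])
  else times[1]
  last <- if (i2 < n)
    times[i2] + (values[i2] - thr) / (values[i2] - values[i2 + 1]) *
      (times[i2 + 1] - times[i2])
  else times[n]
  list(detected = TRUE, first = first, last = last, threshold = thr)
}

#' Measure the cisternal residence time of a tagged protein
#'
#' The residence time is the interval between the first and last visible
#' signals on one maturing cisterna. "Visible" is made operational as signal
#' exceeding background + `k` x noise SD for at least `m` consecutive frames
#' (defaults k = 3, m = 2); the boundary times are refined by linear
#' interpolation of the threshold crossing adjacent to the first/last
#' qualifying frame. Background defaults to the 25th intensity percentile and
#' the noise SD to a robust first-difference estimate, so the detection is
#' invariant under positive scaling of the trace. Traces with no qualifying
#' frames are flagged undetected, not assigned zero.
#'
#' @param trace a [cisterna_trace()] (bleach-corrected upstream if needed).
#' @param channel channel to analyze.
#' @param k detection threshold in noise SDs above background.
#' @param m minimum consecutive frames above threshold.
#' @param background,noise_sd optional explicit background level and noise SD
#'   (otherwise estimated from the trace).
#' @return list of class `residence_record`: `cisterna_id`, `condition`,
#'   `first_visible`, `last_visible`, `residence_time` (s; `NA` when
#'   undetected) and `detected`.
#' @examples
#' tr <- generate_trace(trace_config(noise_sd = 0, timing_jitter_sd = 0,
#'                                   arrival_time = 10, rise_duration = 20,
#'                                   plateau_duration = 50,
#'                                   fall_duration = 20, n_frames = 60))
#' residence_time(tr)$residence_time  # exactly 90 s
#' @export
residence_time <- function(trace, channel = names(trace$channels)[1], k = 3,
                           m = 2, background = NULL, noise_sd = NULL) {
  stopifnot(inherits(trace, "cisterna_trace"))
  det <- detect_visible(trace$times, trace$channels[[channel]], k = k, m = m,
                        background = background, noise_sd = noise_sd)
  structure(
    list(cisterna_id = trace$cisterna_id, condition = trace$condition,
         first_visible = det$first, last_visible = det$last,
         residence_time = if (det$detected) det$last - det$first else NA_real_,
         detected = det$detected),
    class = "residence_record"
  )
}

#' Residence times for a list of traces, as a tibble
#'
#' @param traces list of [cisterna_trace()] objects.
#' @inheritParams residence_time
#' @return tibble with columns `cisterna_id`, `condition`, `first_visible`,
#'   `last_visible`, `residence_time`, `detected`.
#' @export
residence_table <- function(traces, channel = NULL, k = 3, m = 2) {
  rows <- lapply(traces, function(tr) {
    ch <- channel %||% names(tr$channels)[1]
    r <- residence_time(tr, channel = ch, k = k, m = m)
    tibble::tibble(cisterna_id = r$cisterna_id, condition = r$condition,
                   first_visible = r$first_visible,
                   last_visible = r$last_visible,
                   residence_time = r$residence_time, detected = r$detected)
  })
  do.call(rbind, rows)
}

#' Extract and rescale a kinetic-overlap window
#'
#' For two channels with detectable visible periods, the overlap period is
#' the intersection of their visible intervals; signals are extracted over
#' `[overlap_start - w, overlap_end + w]` (clipped to the recording) and each
#' channel is divided by its own maximum within the window, so both rescaled
#' maxima equal 1 exactly.
#'
#' @param trace_a a [cisterna_trace()] carrying the first channel.
#' @param trace_b a trace carrying the second channel; defaults to `trace_a`
#'   (two channels of the same cisterna).
#' @param w window padding before/after the overlap, s; must lie in
#'   `[10, 15]`.
#' @param channel_a,channel_b channel names.
#' @param k,m detection parameters (see [residence_time()]).
#' @return list of class `overlap_window`: `times`, `a`, `b` (rescaled
#'   values), `overlap` (`c(start, end)`), `window` (`c(lo, hi)`).
#' @export
overlap_window <- function(trace_a, trace_b = NULL, w = 12,
                           channel_a = names(trace_a$channels)[1],
                           channel_b = NULL, k = 3, m = 2) {
  trace_b <- trace_b %||% trace_a
  channel_b <- channel_b %||%
    setdiff(names(trace_b$channels), if (identical(trace_b, trace_a)) channel_a else character(0))[1]
  if (w < 10 || w > 15) stop("`w` must be between 10 and 15 s")
  if (!isTRUE(all.equal(trace_a$times, trace_b$times)))
    stop("traces must share a time axis")
  da <- detect_visible(trace_a$times, trace_a$channels[[channel_a]], k, m)
  db <- detect_visible(trace_b$times, trace_b$channels[[channel_b]], k, m)
  if (!da$detected || !db$detected) stop("channel without detectable period")
  o_start <- max(da$first, db$first)
  o_end <- min(da$last, db$last)
  if (o_start >= o_end) stop("no overlap between the two channels")
  lo <- max(trace_a$times[1], o_start - w)
  hi <- min(tail(trace_a$times, 1), o_end + w)
  inside <- trace_a$times >= lo - 1e-9 & trace_a$times <= hi + 1e-9
  a <- trace_a$channels[[channel_a]][inside]
  b <- trace_b$channels[[channel_b]][inside]
  structure(
    list(times = trace_a$times[inside], a = a / max(a), b = b / max(b),
         overlap = c(start = o_start, end = o_end), window = c(lo = lo, hi = hi),
         channels = c(channel_a, channel_b)),
    class = "overlap_window"
  )
}

#' Compare residence times between two conditions
#'
#' Group means and SDs, the treated/control fold change, and Welch's t test
#' (two-sided), as used for partial COPI-inactivation comparisons.
#'
#' @param control,treated numeric vectors of residence times (s), or tibbles
#'   from [residence_table()] (the `residence_time` column is used, dropping
#'   undetected records).
#' @return list of class `condition_comparison`: `summary` (tibble with
#'   group, n, mean, sd), `fold_change` (treated mean / control mean),
#'   `t`, `df`, `p_value`, `label` (significance stars).
#' @export
compare_conditions <- function(control, treated) {
  pull_values <- function(x) {
    if (is.data.frame(x)) x <- x$residence_time[!is.na(x$residence_time)]
    as.numeric(x)
  }
  a <- pull_values(control); b <- pull_values(treated)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 records")
  # fold change is reportable even when the test is degenerate (two
  # constant groups); the Welch statistics are then NA with a warning
  w <- tryCatch(welch_t(a, b), error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    list(t = NA_real_, df = NA_real_, p_value = NA_real_)
  })
  structure(
    list(summary = tibble::tibble(
           group = c("control", "treated"), n = c(length(a), length(b)),
           mean = c(mean(a), mean(b)), sd = c(sd(a), sd(b))),
         fold_change = mean(b) / mean(a),
         t = w$t, df = w$df, p_value = w$p_value,
         label = if (is.na(w$p_value)) NA_character_
                 else significance_label(w$p_value)),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf(
    "<condition_comparison> fold change %.3f, Welch t = %.3f (df %.1f), p = %.3g (%s)\n",
    x$fold_change, x$t, x$df, x$p_value, x$label))
  print(x$summary)
  invisible(x)
}
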