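make_trace <- function(values, dt = 2, channel = "green", id = "t1") {
  cisterna_trace((seq_along(values) - 1) * dt,
                 stats::setNames(list(values), channel), cisterna_id = id)
}

test_that("bleach correction inverts an exponential and preserves ratios", {
  t <- seq(0, 98, by = 2)
  decay <- exp(-0.01 * t)
  tr <- cisterna_trace(t, list(green = 50 * decay, red = 20 * decay))
  corr <- bleach_correct(tr)
  expect_equal(corr$channels$green, rep(50, length(t)), tolerance = 1e-8)
  expect_equal(attr(corr, "bleach_rate"), 0.01, tolerance = 1e-8)
  # per-timepoint channel ratios are untouched
  expect_equal(corr$channels$green / corr$channels$red,
               tr$channels$green / tr$channels$red)

  # no bleaching -> identity
  tr0 <- cisterna_trace(t, list(green = rep(7, length(t))))
  expect_equal(bleach_correct(tr0)$channels$green, tr0$channels$green,
               tolerance = 1e-10)
  expect_error(bleach_correct(cisterna_trace(0:3, list(g = 1:4))), "5 timepoints")
})

test_that("boxcar smoothing shrinks at endpoints", {
  expect_equal(smooth_trace(c(0, 0, 3, 0, 0), 3), c(0, 1, 1, 1, 0))
  expect_equal(smooth_trace(c(4, 1, 7), 1), c(4, 1, 7))
  expect_equal(smooth_trace(rep(2, 9), 5), rep(2, 9))
  tr <- make_trace(c(0, 0, 3, 0, 0))
  expect_equal(smooth_trace(tr, 3)$channels$green, c(0, 1, 1, 1, 0))
  expect_error(smooth_trace(c(1, 2), 3), "exceeds")
  expect_error(smooth_trace(1:5, 2), "odd")
})

test_that("normalization is exact, idempotent and affine-invariant", {
  expect_equal(normalize_trace(c(10, 10, 40, 70, 10)), c(0, 0, 0.5, 1, 0))
  x <- c(0, 0, 0.5, 1, 0)
  expect_equal(normalize_trace(x), x)                      # already normalized
  y <- c(3, 5, 20, 60, 80, 75, 30, 6, 4)
  n1 <- normalize_trace(y)
  expect_equal(normalize_trace(n1), n1)                    # idempotent
  expect_equal(normalize_trace(2.5 * y + 17), n1)          # affine invariant
  expect_equal(max(n1), 1)
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_error(normalize_trace(rep(3, 10)), "no dynamic range")
})

test_that("alignment recovers injected shifts exactly and averages bounded", {
  base <- generate_trace(trace_config(noise_sd = 0, timing_jitter_sd = 0),
                         channel = "green")
  shifts <- c(0, 4.6, -3.2)
  traces <- lapply(seq_along(shifts), function(i) {
    tr <- base
    tr$times <- base$times + shifts[i]
    tr$cisterna_id <- paste0("c", i)
    tr
  })
  avg <- align_traces(traces, "green")
  lm <- attr(avg, "landmarks")
  expect_equal(lm - lm[1], shifts, tolerance = 1e-10)      # shifts recovered
  expect_true(all(avg$mean >= 0 & avg$mean <= 1))
  expect_true(all(avg$n >= 1))
  # where all three traces contribute, they agree exactly (same shape)
  expect_true(all(avg$sd[avg$n == 3] < 1e-10))

  # permutation invariance
  avg2 <- align_traces(traces[c(3, 1, 2)], "green")
  expect_equal(avg$mean, avg2$mean)

  # two identical traces average to the (interpolated) trace itself
  two <- align_traces(list(traces[[1]], traces[[1]]), "green")
  ref <- normalize_trace(base$channels$green)
  t0 <- two$time + lm[1] - shifts[1]
  expect_equal(two$mean, approx(base$times, ref, xout = t0)$y)
})

test_that("traces without a half-max crossing are excluded with a warning", {
  good <- generate_trace(trace_config(noise_sd = 0, timing_jitter_sd = 0))
  flat_high <- good
  flat_high$channels$green <- rev(sort(good$channels$green))  # starts at max
  flat_high$cisterna_id <- "bad"
  expect_warning(
    avg <- align_traces(list(good, good, flat_high), "green"),
    "excluded")
  expect_length(attr(avg, "landmarks"), 2)
  expect_error(suppressWarnings(align_traces(list(good, flat_high), "green")),
               "fewer than 2")
})

test_that("residence time is exact on clean data and flags silence", {
  tr <- generate_trace(trace_config(arrival_time = 10, rise_duration = 20,
                                    plateau_duration = 50, fall_duration = 20,
                                    noise_sd = 0, timing_jitter_sd = 0,
                                    n_frames = 60))
  r <- residence_time(tr)
  expect_equal(r$residence_time, 90)
  expect_equal(r$first_visible, 10)
  expect_equal(r$last_visible, 100)

  silent <- make_trace(rep(0, 50))
  rs <- residence_time(silent)
  expect_false(rs$detected)
  expect_true(is.na(rs$residence_time))

  # invariance under positive scaling (threshold scales with the trace)
  noisy <- generate_trace(trace_config(rng_seed = 11))
  scaled <- noisy
  scaled$channels$green <- 5 * noisy$channels$green
  expect_equal(residence_time(scaled)$residence_time,
               residence_time(noisy)$residence_time)
})

test_that("overlap windows use interval arithmetic and unit maxima", {
  t <- seq(0, 90, by = 2)
  a <- ifelse(t <= 48, 1, ifelse(t < 50, (50 - t) / 2, 0))  # visible [0, 50]
  b <- ifelse(t <= 40, 0, ifelse(t < 42, (t - 40) / 2, 1))  # visible [40, 90]
  tr <- cisterna_trace(t, list(first = a, second = b))
  ow <- overlap_window(tr, w = 10)
  expect_equal(unname(ow$overlap), c(40, 50))
  expect_equal(unname(ow$window), c(30, 60))
  expect_identical(max(ow$a), 1)
  expect_identical(max(ow$b), 1)

  # identical channels: full mutual overlap, identical rescaled traces
  tr2 <- generate_trace(trace_config(noise_sd = 0, timing_jitter_sd = 0))
  tr2$channels$red <- tr2$channels$green
  ow2 <- overlap_window(tr2, w = 12, channel_a = "green", channel_b = "red")
  expect_identical(ow2$a, ow2$b)
  expect_identical(max(ow2$a), 1)

  # disjoint channels -> error
  c1 <- ifelse(t < 20, 1, 0); c2 <- ifelse(t > 70, 1, 0)
  tr3 <- cisterna_trace(t, list(x = c1, y = c2))
  expect_error(overlap_window(tr3, w = 10), "no overlap")
  expect_error(overlap_window(tr, w = 5), "between 10 and 15")
})

test_that("condition comparison reports folds and Welch statistics", {
  idn <- compare_conditions(c(90, 94, 98), c(90, 94, 98))
  expect_equal(idn$fold_change, 1)
  expect_equal(idn$t, 0)
  expect_equal(idn$p_value, 1)

  expect_warning(
    cc <- compare_conditions(c(90, 90, 90), c(135, 135, 135)),
    "degenerate")
  expect_equal(cc$fold_change, 1.5)

  expect_error(compare_conditions(90, c(1, 2, 3)), "at least 2")
})
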