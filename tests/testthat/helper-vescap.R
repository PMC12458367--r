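# shared fixtures, built in code

# tiny hand-constructible stack: explicit per-channel arrays
toy_stack <- function(red, green, blue, px = 60, zs = 300) {
  channel_stack(list(red = red, green = green, blue = blue),
                voxel_size_xy = px, z_step = zs)
}

const_array <- function(value, dims = c(6, 6, 3)) array(value, dims)

# trapezoid sampled like generate_trace but computed independently here
# (piecewise-linear closed form) for use as an oracle
trapezoid_oracle <- function(times, t0, rise, plateau, fall, amp) {
  sapply(times, function(t) {
    tt <- t - t0
    if (tt <= 0) 0
    else if (tt < rise) amp * tt / rise
    else if (tt <= rise + plateau) amp
    else if (tt < rise + plateau + fall) amp * (1 - (tt - rise - plateau) / fall)
    else 0
  })
}

# closed-form Welch statistic, independent of stats::t.test
welch_oracle <- function(a, b) {
  sa <- var(a) / length(a); sb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
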