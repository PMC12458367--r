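# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic integer seed (< 2^31) from an arbitrary key.
key_to_seed <- function(key) {
  chars <- utf8ToInt(paste0("k:", paste(as.character(key), collapse = "|")))
  s <- 0
  for (ch in chars) s <- (s * 131 + ch) %% 2147483629
  as.integer(s)
}

stopifnot_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict && x <= min) stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  if (!strict && x < min) stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  invisible(x)
}

# shrink-at-endpoints boxcar used by smooth_trace
boxcar <- function(x, window) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}
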