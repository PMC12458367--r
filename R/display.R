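#' Prepare a composite image for blinded categorical scoring
#'
#' Average z-projection of each channel, per-channel contrast enhancement by
#' clipping a fixed percentage of the brightest pixels (0.3% red, 0.5% green,
#' 0.4% blue by default) followed by linear rescale to `[0, 1]`, then an RGB
#' merge.
#'
#' The saturation rule clips exactly `ceiling(sat * n)` pixels on an
#' `n`-pixel channel: the cutoff is the next-ranked pixel value, so every
#' strictly brighter pixel maps to 1.
#'
#' @param stack a [channel_stack()].
#' @param saturation named numeric vector of per-channel saturated-pixel
#'   fractions.
#' @return `ny x nx x 3` array in `[0, 1]` (R, G, B planes).
#' @export
enhance_for_categorical <- function(stack,
                                    saturation = c(red = 0.003, green = 0.005,
                                                   blue = 0.004)) {
  stopifnot(inherits(stack, "channel_stack"))
  d <- dim(stack$voxels)
  out <- array(0, c(d[1], d[2], 3L))
  for (i in seq_along(c("red", "green", "blue"))) {
    ch <- c("red", "green", "blue")[i]
    proj <- apply(get_channel(stack, ch), c(1, 2), mean)
    out[, , i] <- saturate_rescale(proj, saturation[[ch]])
  }
  out
}

# clip the top `sat` fraction of pixels, rescale linearly to [0, 1]
saturate_rescale <- function(img, sat) {
  v <- as.vector(img)
  n <- length(v)
  lo <- min(v)
  n_sat <- min(n - 1L, max(0L, ceiling(sat * n)))
  srt <- sort(v, decreasing = TRUE)
  hi <- srt[n_sat + 1L]
  if (hi <= lo) return(array(0, dim(img)))
  out <- (img - lo) / (hi - lo)
  out[out > 1] <- 1
  out[out < 0] <- 0
  out
}

#' Scale an image for figure display
#'
#' Min-max rescale to the full dynamic range, multiply by 1.5 so faint
#' structures stay visible, and clip at the range maximum. A constant image
#' has no dynamic range and maps to 0.
#'
#' @param image numeric 2D matrix (or array).
#' @param max_value top of the dynamic range (1 for normalized images, 255
#'   for 8-bit).
#' @return image on `[0, max_value]`.
#' @examples
#' scale_display(matrix(c(0, 100), 1), max_value = 255)
#' @export
scale_display <- function(image, max_value = 1) {
  stopifnot_scalar_num(max_value, "max_value", 0, strict = TRUE)
  rng <- range(image)
  if (diff(rng) == 0) return(array(0, dim(image) %||% length(image)))
  y <- (image - rng[1]) / diff(rng) * max_value * 1.5
  y[y > max_value] <- max_value
  y
}

#' Blind image names for unbiased scoring
#'
#' Deterministic, key-reversible renaming: the key seeds a pseudorandom
#' permutation and each original name maps to an opaque label
#' (`blind_001`, ...). Blinded names carry no condition information; the
#' inverse map restores identities after scoring.
#'
#' @param names character vector of unique image names.
#' @param key scalar key (string or number); the same key always reproduces
#'   the same mapping.
#' @return list with `forward` (named character: original -> blinded) and
#'   `inverse` (blinded -> original).
#' @export
blind_names <- function(names, key) {
  if (anyDuplicated(names)) stop("image names must be unique")
  n <- length(names)
  perm <- with_seed(key_to_seed(key), sample.int(n))
  blinded <- sprintf("blind_%0*d", max(3L, nchar(n)), perm)
  forward <- stats::setNames(blinded, names)
  inverse <- stats::setNames(names, blinded)
  list(forward = forward, inverse = inverse)
}
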