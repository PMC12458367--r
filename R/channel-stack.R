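#' Three-channel confocal stack
#'
#' Container for a 3-channel 3D voxel grid with physical voxel sizes, the unit
#' the capture assay quantifies. Channel roles follow the assay convention:
#' red = septin (bud-neck ring), green = cargo (GFP-tagged Golgi protein),
#' blue = Golgi marker (far-red HaloTag signal is mapped onto the blue slot).
#'
#' @param voxels numeric array, either `c(ny, nx, nz, 3)` or a list of three
#'   `c(ny, nx, nz)` arrays named `red`, `green`, `blue`. Intensities must be
#'   non-negative and finite.
#' @param voxel_size_xy lateral voxel size in nm.
#' @param z_step axial step between optical sections in nm.
#' @return An object of class `channel_stack` with elements `voxels`
#'   (`ny x nx x nz x 3` array, channel dimnames `red`, `green`, `blue`),
#'   `voxel_size_xy` and `z_step`.
#' @examples
#' vox <- array(0, c(8, 8, 3, 3))
#' stk <- channel_stack(vox, voxel_size_xy = 60, z_step = 300)
#' dim(stk$voxels)
#' @export
channel_stack <- function(voxels, voxel_size_xy, z_step) {
  if (is.list(voxels)) {
    if (!all(c("red", "green", "blue") %in% names(voxels)))
      stop("channel list must be named red, green, blue")
    d <- dim(voxels$red)
    voxels <- array(c(voxels$red, voxels$green, voxels$blue), c(d, 3L))
  }
  if (length(dim(voxels)) != 4L || dim(voxels)[4] != 3L)
    stop("`voxels` must be a ny x nx x nz x 3 array")
  if (any(!is.finite(voxels)) || any(voxels < 0))
    stop("intensities must be finite and >= 0")
  stopifnot_scalar_num(voxel_size_xy, "voxel_size_xy", 0, strict = TRUE)
  stopifnot_scalar_num(z_step, "z_step", 0, strict = TRUE)
  dimnames(voxels) <- list(NULL, NULL, NULL, c("red", "green", "blue"))
  structure(
    list(voxels = voxels, voxel_size_xy = voxel_size_xy, z_step = z_step),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<channel_stack> %d x %d pixels, %d slices, 3 channels (%g nm px, %g nm z-step)\n",
    d[1], d[2], d[3], x$voxel_size_xy, x$z_step
  ))
  invisible(x)
}

# single channel as 3D array
get_channel <- function(stack, channel = c("red", "green", "blue")) {
  channel <- match.arg(channel)
  stack$voxels[, , , channel, drop = TRUE]
}

#' Whole-volume region of interest
#'
#' Convenience ROI (per-slice binary region) covering the entire stack, used
#' when the field of view contains a single mother-daughter pair.
#'
#' @param stack a [channel_stack()].
#' @return logical `ny x nx x nz` array, all `TRUE`.
#' @export
full_roi <- function(stack) {
  array(TRUE, dim(stack$voxels)[1:3])
}

check_roi <- function(roi, stack) {
  if (is.null(roi)) return(full_roi(stack))
  if (!is.logical(roi) || !identical(dim(roi), dim(stack$voxels)[1:3]))
    stop("`roi` must be a logical array matching the stack's spatial dimensions")
  if (!any(roi)) stop("`roi` is empty")
  roi
}

#' Write / read a channel stack as multi-page TIFF with a JSON sidecar
#'
#' One 32-bit float multi-page TIFF per channel (`<prefix>_red.tif`, ...),
#' z-slices as pages, plus `<prefix>_meta.json` recording voxel sizes and the
#' intensity scale (TIFF pages are stored on a 0-1 scale; `intensity_scale`
#' restores counts on read).
#'
#' @param stack a [channel_stack()].
#' @param prefix output path prefix.
#' @return `write_channel_stack()` returns the sidecar path invisibly;
#'   `read_channel_stack()` returns a [channel_stack()].
#' @export
write_channel_stack <- function(stack, prefix) {
  scale <- max(stack$voxels, 1e-12)
  for (ch in c("red", "green", "blue")) {
    v <- get_channel(stack, ch) / scale
    pages <- lapply(seq_len(dim(v)[3]), function(z) v[, , z])
    tiff::writeTIFF(pages, paste0(prefix, "_", ch, ".tif"), bits.per.sample = 32L)
  }
  meta <- list(
    voxel_size_xy_nm = stack$voxel_size_xy, z_step_nm = stack$z_step,
    intensity_scale = scale, channels = c("red", "green", "blue"),
    layout = "one multi-page float TIFF per channel, pages are z-slices"
  )
  path <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_channel_stack
#' @export
read_channel_stack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  chans <- lapply(c("red", "green", "blue"), function(ch) {
    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"), all = TRUE)
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
    arr * meta$intensity_scale
  })
  names(chans) <- c("red", "green", "blue")
  channel_stack(chans, meta$voxel_size_xy_nm, meta$z_step_nm)
}
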