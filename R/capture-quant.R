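#' Generate a ladder of threshold options for one channel
#'
#' Deterministic, contrast-adaptive stand-in for an interactive threshold
#' chooser. Levels are built from robust background statistics of the channel
#' within the ROI: a scale estimate `s = max(MAD, 0.05 * (max - median))` (the
#' range-based floor covers count-valued or two-population data whose MAD is
#' exactly zero), then cutoffs at `median + {2, 4, 8, 16} * s` named
#' `"Basement"` (lowest, most generous mask), `"Lower"`, `"Middle"`,
#' `"Upper"`. In the capture assay the septin (red) mask uses `"Lower"` and
#' the Golgi (blue) mask uses `"Basement"` so that nearly all visible Golgi
#' signal is subtracted.
#'
#' @param channel numeric 3D array (one channel's voxels).
#' @param roi logical array of the same shape (region of interest); `NULL`
#'   uses all voxels.
#' @return named numeric vector of strictly increasing cutoffs, class
#'   `threshold_ladder`.
#' @examples
#' x <- array(10, c(6, 6, 2)); x[3, 3, 1] <- 100
#' generate_threshold_options(x)
#' @export
generate_threshold_options <- function(channel, roi = NULL) {
  if (is.null(roi)) roi <- array(TRUE, dim(channel))
  if (!any(roi)) stop("ROI is empty")
  v <- channel[roi]
  med <- median(v)
  s <- max(mad(v), 0.05 * (max(v) - med))
  if (s <= 0) stop("no contrast: channel is constant within the ROI")
  cuts <- med + c(Basement = 2, Lower = 4, Middle = 8, Upper = 16) * s
  structure(cuts, class = "threshold_ladder")
}

ladder_cutoff <- function(ladder, level) {
  if (is.numeric(level) && is.null(names(level)) && !inherits(level, "threshold_ladder"))
    return(as.numeric(level))
  if (!level %in% names(ladder))
    stop(sprintf("unknown threshold level '%s' (have: %s)", level,
                 paste(names(ladder), collapse = ", ")))
  unname(ladder[[level]])
}

#' Build a per-slice binary mask by thresholding
#'
#' Mask is `voxels >= cutoff` (inclusive comparator) restricted to the ROI,
#' evaluated voxelwise so each z-slice is masked independently (no
#' projection).
#'
#' @param channel numeric 3D array.
#' @param cutoff scalar intensity cutoff.
#' @param roi logical array or `NULL` for the whole grid.
#' @return logical array of the channel's shape.
#' @export
build_mask <- function(channel, cutoff, roi = NULL) {
  stopifnot_scalar_num(cutoff, "cutoff")
  m <- channel >= cutoff
  if (!is.null(roi)) {
    if (!identical(dim(roi), dim(channel))) stop("ROI shape mismatch")
    m <- m & roi
  }
  m
}

#' Subtract the Golgi mask from the septin mask
#'
#' The septin mask is modified by removing every voxel also covered by the
#' Golgi mask, ensuring that Golgi cisternae sitting at the bud neck do not
#' contribute to the capture signal. The removed fraction feeds the cell QC
#' rule ([qc_cell()]).
#'
#' @param septin_mask,golgi_mask logical arrays of identical shape.
#' @return list of class `mask_set`: `septin_mask`, `golgi_mask`,
#'   `modified_mask` (septin AND NOT golgi) and `removed_fraction`
#'   (`1 - |modified| / |septin|`, voxel counts).
#' @export
subtract_mask <- function(septin_mask, golgi_mask) {
  if (!identical(dim(septin_mask), dim(golgi_mask)))
    stop("mask shape mismatch")
  n_septin <- sum(septin_mask)
  if (n_septin == 0) stop("no septin signal: septin mask is empty")
  modified <- septin_mask & !golgi_mask
  structure(
    list(septin_mask = septin_mask, golgi_mask = golgi_mask,
         modified_mask = modified,
         removed_fraction = 1 - sum(modified) / n_septin),
    class = "mask_set"
  )
}

#' Cell QC: reject cells with heavy cisternal interference at the neck
#'
#' A cell is analyzable only if subtracting the Golgi mask removed less than
#' 65% of the septin mask; removal of at least 65% indicates Golgi cisternae
#' overlying the bud neck and excludes the cell. The boundary is strict:
#' exactly 0.65 fails.
#'
#' @param removed_fraction fraction of septin-mask voxels removed, in
#'   `[0, 1]`.
#' @return `TRUE` (pass) iff `removed_fraction < 0.65`.
#' @export
qc_cell <- function(removed_fraction) {
  stopifnot_scalar_num(removed_fraction, "removed_fraction")
  if (removed_fraction < 0 || removed_fraction > 1)
    stop("`removed_fraction` must be in [0, 1]")
  removed_fraction < 0.65
}

#' Quantify co-capture of cargo at the bud neck
#'
#' The numerical capture statistic. Per z-slice, a septin mask is built from
#' the red channel at `red_level` and a Golgi mask from the blue channel at
#' `blue_level` (levels name entries of each channel's own
#' [generate_threshold_options()] ladder, or may be explicit numeric
#' cutoffs). The Golgi mask is subtracted from the septin mask, green
#' intensity is summed inside the modified mask and inside the whole ROI
#' across all slices, and the capture fraction is their ratio. QC is reported
#' but not enforced: filtering is left to the caller so that excluded cells
#' can be tabulated.
#'
#' @param stack a [channel_stack()].
#' @param roi logical array delimiting the mother-daughter pair; `NULL` for
#'   the full volume.
#' @param red_level,blue_level ladder level names (default `"Lower"` and
#'   `"Basement"`) or numeric cutoffs.
#' @param cell_id,condition labels copied into the result.
#' @return list of class `cell_capture`: `capture_fraction`,
#'   `green_in_mask`, `green_total_in_roi`, `removed_fraction`, `qc_pass`,
#'   `thresholds` (the numeric cutoffs used), `cell_id`, `condition`.
#' @examples
#' sc <- generate_capture_scene(scene_config(rng_seed = 11))
#' res <- quantify_overlap(sc$stack)
#' c(estimate = res$capture_fraction, truth = sc$truth$true_capture_fraction)
#' @export
quantify_overlap <- function(stack, roi = NULL, red_level = "Lower",
                             blue_level = "Basement",
                             cell_id = NA_character_,
                             condition = NA_character_) {
  stopifnot(inherits(stack, "channel_stack"))
  roi <- check_roi(roi, stack)
  red <- get_channel(stack, "red")
  green <- get_channel(stack, "green")
  blue <- get_channel(stack, "blue")

  red_cut <- if (is.character(red_level))
    ladder_cutoff(generate_threshold_options(red, roi), red_level) else as.numeric(red_level)
  blue_cut <- if (is.character(blue_level))
    ladder_cutoff(generate_threshold_options(blue, roi), blue_level) else as.numeric(blue_level)

  masks <- subtract_mask(build_mask(red, red_cut, roi),
                         build_mask(blue, blue_cut, roi))
  green_total <- sum(green[roi])
  if (green_total <= 0) stop("empty green channel: no green signal in the ROI")
  green_in <- sum(green[masks$modified_mask])
  structure(
    list(capture_fraction = green_in / green_total,
         green_in_mask = green_in, green_total_in_roi = green_total,
         removed_fraction = masks$removed_fraction,
         qc_pass = qc_cell(masks$removed_fraction),
         thresholds = c(red = red_cut, blue = blue_cut),
         cell_id = cell_id, condition = condition),
    class = "cell_capture"
  )
}

#' @export
print.cell_capture <- function(x, ...) {
  cat(sprintf(
    "<cell_capture> %s: capture fraction %.4f (removed %.1f%% of septin mask, QC %s)\n",
    x$cell_id, x$capture_fraction, 100 * x$removed_fraction,
    if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}

#' @export
as.data.frame.cell_capture <- function(x, ...) {
  data.frame(cell_id = x$cell_id, condition = x$condition,
             removed_fraction = x$removed_fraction, qc_pass = x$qc_pass,
             capture_fraction = x$capture_fraction)
}

#' Collect per-cell capture results into a tibble
#'
#' @param results list of `cell_capture` objects from [quantify_overlap()].
#' @return tibble with one row per cell: `cell_id`, `condition`,
#'   `removed_fraction`, `qc_pass`, `capture_fraction`.
#' @export
capture_results_table <- function(results) {
  tibble::as_tibble(do.call(rbind, lapply(results, as.data.frame)))
}
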