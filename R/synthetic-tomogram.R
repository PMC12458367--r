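#' Configuration for a synthetic tomogram vesicle model
#'
#' A cortex polyline through the bud neck plus randomly placed spherical
#' non-secretory vesicles (radii drawn uniformly from 17.5-30 nm, the
#' ~35-60 nm diameter class), each labeled captured / not-captured by the
#' dense surface-sampling reference classifier against the capture zone
#' built from this same configuration.
#'
#' @param cortex a [cortex_model()]; default a gently curved arc
#'   ([make_arc_cortex()]).
#' @param n_vesicles number of vesicles.
#' @param vesicle_radius_range nm, `c(min, max)` of uniform radii.
#' @param placement_region list with `x`, `y`, `z` ranges (nm) bounding the
#'   vesicle centers; default straddles the zone so both labels occur.
#' @param depth zone depth, nm (default `zone_depth(48, 58)` = 106).
#' @param arc zone half-extent along the cortex, nm.
#' @param oracle_points surface sample points per vesicle for truth labels.
#' @param rng_seed integer seed.
#' @return list of class `tomogram_config`.
#' @export
tomogram_config <- function(cortex = make_arc_cortex(),
                            n_vesicles = 30,
                            vesicle_radius_range = c(17.5, 30),
                            placement_region = list(x = c(-450, 450),
                                                    y = c(0, 350),
                                                    z = c(-100, 100)),
                            depth = zone_depth(48, 58), arc = 200,
                            oracle_points = 10000, rng_seed = 1L) {
  stopifnot(inherits(cortex, "cortex_model"))
  if (any(vesicle_radius_range <= 0) || diff(vesicle_radius_range) < 0)
    stop("invalid `vesicle_radius_range`")
  structure(
    list(cortex = cortex, n_vesicles = as.integer(n_vesicles),
         vesicle_radius_range = vesicle_radius_range,
         placement_region = placement_region, depth = depth, arc = arc,
         oracle_points = oracle_points, rng_seed = as.integer(rng_seed)),
    class = "tomogram_config"
  )
}

#' Generate a synthetic tomogram vesicle model with truth labels
#'
#' @param config a [tomogram_config()].
#' @return list with `cortex`, `zone` (the [build_capture_zone()] built from
#'   the config), `vesicles` (tibble: `cell_id`, `x_nm`, `y_nm`, `z_nm`,
#'   `radius_nm`, `class`) and `true_captured` (logical vector from the
#'   surface-sampling classifier).
#' @examples
#' tm <- generate_tomogram_model(tomogram_config(n_vesicles = 5))
#' sum(tm$true_captured)
#' @export
generate_tomogram_model <- function(config) {
  stopifnot(inherits(config, "tomogram_config"))
  zone <- build_capture_zone(config$cortex, config$depth, config$arc)
  with_seed(config$rng_seed, {
    pr <- config$placement_region
    n <- config$n_vesicles
    ves <- tibble::tibble(
      cell_id = "cell1",
      x_nm = stats::runif(n, pr$x[1], pr$x[2]),
      y_nm = stats::runif(n, pr$y[1], pr$y[2]),
      z_nm = stats::runif(n, pr$z[1], pr$z[2]),
      radius_nm = stats::runif(n, config$vesicle_radius_range[1],
                               config$vesicle_radius_range[2]),
      class = "non-secretory"
    )
    truth <- vapply(seq_len(n), function(j) {
      classify_vesicle_sampled(c(ves$x_nm[j], ves$y_nm[j], ves$z_nm[j]),
                               ves$radius_nm[j], zone,
                               n_points = config$oracle_points)
    }, logical(1))
    list(cortex = config$cortex, zone = zone, vesicles = ves,
         true_captured = truth)
  })
}
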