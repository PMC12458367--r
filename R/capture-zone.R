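#' Capture-zone depth from linker lengths
#'
#' The cytoplasm-ward depth of the bud-neck capture zone is the sum of the
#' predicted maximally extended lengths of the FKBP-tagged septin construct
#' and the FRB-tagged cargo cytosolic tail, since a captured vesicle can sit
#' at most one fully extended tether pair away from the plasma membrane.
#'
#' @param septin_construct_length nm (e.g. 48 for the tagged septin).
#' @param cargo_tail_length nm (e.g. 58 for the Kex2 cytosolic tail).
#' @return depth in nm.
#' @examples
#' zone_depth(48, 58)  # 106 nm
#' @export
zone_depth <- function(septin_construct_length, cargo_tail_length) {
  stopifnot_scalar_num(septin_construct_length, "septin_construct_length", 0)
  stopifnot_scalar_num(cargo_tail_length, "cargo_tail_length", 0)
  septin_construct_length + cargo_tail_length
}

#' Plasma-membrane cortex model
#'
#' An ordered 3D polyline (nm) tracing the cell cortex through the bud neck,
#' with the neck center given as an arc-length position and the cytoplasm
#' side declared explicitly as a direction vector. The declared direction
#' disambiguates which side of the membrane the capture zone extends into;
#' zone construction refuses to proceed without it.
#'
#' @param points numeric `n x 3` matrix of cortex coordinates, nm, ordered
#'   along the membrane.
#' @param cytoplasm_direction length-3 vector pointing from the membrane into
#'   the cytoplasm (normalized internally).
#' @param neck_arclength arc-length position (nm) of the bud-neck center
#'   along the polyline; defaults to the midpoint.
#' @return object of class `cortex_model` with `points`, `arclength`
#'   (cumulative, nm), `neck_arclength`, `cytoplasm_direction`.
#' @export
cortex_model <- function(points, cytoplasm_direction = NULL,
                         neck_arclength = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 2)
    stop("degenerate polyline: need an n x 3 matrix with n >= 2")
  seg <- diff(points)
  len <- sqrt(rowSums(seg^2))
  if (any(len <= 0)) stop("degenerate polyline: zero-length segment")
  s <- c(0, cumsum(len))
  if (!is.null(cytoplasm_direction)) {
    nv <- sqrt(sum(cytoplasm_direction^2))
    if (length(cytoplasm_direction) != 3 || nv <= 0)
      stop("`cytoplasm_direction` must be a nonzero length-3 vector")
    cytoplasm_direction <- cytoplasm_direction / nv
  }
  neck_arclength <- neck_arclength %||% (s[length(s)] / 2)
  if (neck_arclength < 0 || neck_arclength > s[length(s)])
    stop("`neck_arclength` outside the polyline")
  structure(
    list(points = unname(points), arclength = s,
         neck_arclength = neck_arclength,
         cytoplasm_direction = cytoplasm_direction),
    class = "cortex_model"
  )
}

# point at arc-length position s along the polyline
polyline_point <- function(points, arcs, s) {
  i <- findInterval(s, arcs, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(points) - 1L)
  f <- (s - arcs[i]) / (arcs[i + 1] - arcs[i])
  points[i, ] + f * (points[i + 1, ] - points[i, ])
}

# sub-polyline between arc lengths [lo, hi], endpoints interpolated
clip_polyline <- function(points, arcs, lo, hi) {
  inner <- which(arcs > lo & arcs < hi)
  rbind(polyline_point(points, arcs, lo),
        points[inner, , drop = FALSE],
        polyline_point(points, arcs, hi))
}

#' Build the bud-neck capture zone
#'
#' The zone is constructed in two steps: (a) the cortex segment extending
#' `arc` nm in each direction along the membrane from the neck center, and
#' (b) the region extending `depth` nm from that segment into the cytoplasm.
#' Geometrically the zone is the Minkowski-style inward offset of the cortex
#' segment: the union, over every point of the segment, of the
#' cytoplasm-side half-ball of radius `depth` oriented along the declared
#' cytoplasm direction. The zone is closed, so boundary contact counts as
#' inside.
#'
#' @param cortex a [cortex_model()]; must declare `cytoplasm_direction` and
#'   span at least `arc` of arc length on both sides of the neck center.
#' @param depth zone depth into the cytoplasm, nm (see [zone_depth()]).
#' @param arc half-extent along the cortex, nm (default 200, the measured
#'   reach of the septin ring along the membrane).
#' @return object of class `capture_zone` with the truncated `segment`
#'   polyline, `depth`, `arc`, `normal` (cytoplasm direction).
#' @export
build_capture_zone <- function(cortex, depth, arc = 200) {
  stopifnot(inherits(cortex, "cortex_model"))
  stopifnot_scalar_num(depth, "depth", 0, strict = TRUE)
  stopifnot_scalar_num(arc, "arc", 0, strict = TRUE)
  if (is.null(cortex$cytoplasm_direction))
    stop(paste("ambiguous normal orientation: declare `cytoplasm_direction`",
               "on the cortex model"))
  s0 <- cortex$neck_arclength
  total <- cortex$arclength[length(cortex$arclength)]
  if (s0 - arc < -1e-9 || s0 + arc > total + 1e-9)
    stop(sprintf("cortex polyline too short: need +/-%g nm of arc around the neck", arc))
  seg <- clip_polyline(cortex$points, cortex$arclength,
                       max(0, s0 - arc), min(total, s0 + arc))
  structure(
    list(segment = seg, depth = depth, arc = arc,
         normal = cortex$cytoplasm_direction),
    class = "capture_zone"
  )
}

#' Test points for capture-zone membership
#'
#' Closed-form membership: a point is inside iff, for some cortex segment
#' piece, there is a parameter t with the point within `depth` of the piece
#' (a quadratic interval in t) on the cytoplasm side of the membrane (a
#' half-space interval in t). The zone is closed (boundary included).
#'
#' @param points numeric `n x 3` matrix (or length-3 vector), nm.
#' @param zone a [build_capture_zone()] result.
#' @return logical vector of length `n`.
#' @export
point_in_zone <- function(points, zone) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  points <- as.matrix(points)
  seg <- zone$segment; N <- zone$normal; d2 <- zone$depth^2
  inside <- rep(FALSE, nrow(points))
  for (i in seq_len(nrow(seg) - 1L)) {
    todo <- which(!inside)
    if (!length(todo)) break
    a <- seg[i, ]; u <- seg[i + 1, ] - a
    L2 <- sum(u^2)
    w <- sweep(points[todo, , drop = FALSE], 2, a)
    wu <- as.vector(w %*% u)
    wn <- as.vector(w %*% N)
    un <- sum(u * N)
    disc <- wu^2 - L2 * (rowSums(w^2) - d2)
    # closed-region convention: admit exact-boundary contacts lost to
    # floating-point cancellation
    tol <- 1e-9 * (wu^2 + L2 * abs(rowSums(w^2) - d2) + 1)
    has <- disc >= -tol
    t1 <- pmax(0, (wu - sqrt(pmax(disc, 0))) / L2)
    t2 <- pmin(1, (wu + sqrt(pmax(disc, 0))) / L2)
    # cytoplasm-side constraint wn - t*un >= 0 as an interval in t
    if (abs(un) < 1e-12) {
      ok <- has & t1 <= t2 & wn >= 0
    } else if (un > 0) {
      ok <- has & t1 <= pmin(t2, wn / un)
    } else {
      ok <- has & pmax(t1, wn / un) <= t2
    }
    inside[todo[ok]] <- TRUE
  }
  inside
}

# distance from v (relative to a cortex point) to that point's half-ball
# of radius d oriented along N
dist_half_ball <- function(v, d, N) {
  h <- sum(v * N)
  if (h >= 0) return(max(0, sqrt(sum(v^2)) - d))
  w <- v - h * N
  rho <- sqrt(sum(w^2))
  if (rho <= d) -h else sqrt((rho - d)^2 + h^2)
}

#' Distance from a point to the capture zone
#'
#' Zero for points inside; otherwise the minimum Euclidean distance to the
#' closed zone, found per cortex segment by a coarse parameter grid refined
#' with [stats::optimize()].
#'
#' @param point length-3 numeric vector, nm.
#' @param zone a [build_capture_zone()] result.
#' @return distance in nm.
#' @export
distance_to_zone <- function(point, zone) {
  if (point_in_zone(point, zone)) return(0)
  seg <- zone$segment; d <- zone$depth; N <- zone$normal
  best <- Inf
  for (i in seq_len(nrow(seg) - 1L)) {
    a <- seg[i, ]; u <- seg[i + 1, ] - a
    g <- function(t) dist_half_ball(point - a - t * u, d, N)
    tg <- seq(0, 1, length.out = 33)
    vals <- vapply(tg, g, numeric(1))
    j <- which.min(vals)
    lo <- tg[max(1L, j - 1L)]; hi <- tg[min(length(tg), j + 1L)]
    opt <- if (hi > lo) optimize(g, c(lo, hi), tol = 1e-10)$objective else vals[j]
    best <- min(best, vals[j], opt)
  }
  best
}

#' Score a vesicle as putatively captured
#'
#' A vesicle counts as captured if any part of its membrane lies within the
#' (closed) capture zone, i.e. if the sphere about its center intersects the
#' zone: distance from center to zone <= radius. Tangency counts as captured.
#'
#' @param center length-3 numeric vector, nm.
#' @param radius vesicle radius, nm.
#' @param zone a [build_capture_zone()] result.
#' @return logical.
#' @export
classify_vesicle <- function(center, radius, zone) {
  stopifnot_scalar_num(radius, "radius", 0, strict = TRUE)
  distance_to_zone(center, zone) <= radius + 1e-9
}

#' Surface-sampling reference classifier
#'
#' Independent check of [classify_vesicle()]: the vesicle surface is sampled
#' with a deterministic Fibonacci lattice (default 10^4 points) and the
#' vesicle is scored captured if the center or any surface point falls inside
#' the zone. Used to label synthetic tomogram models and to cross-validate
#' the distance-based classifier; it can in principle miss grazing contacts
#' smaller than the lattice spacing.
#'
#' @inheritParams classify_vesicle
#' @param n_points number of surface sample points.
#' @return logical.
#' @export
classify_vesicle_sampled <- function(center, radius, zone, n_points = 10000) {
  if (point_in_zone(center, zone)) return(TRUE)
  i <- seq_len(n_points) - 1L
  z <- 1 - (2 * i + 1) / n_points
  theta <- pi * (3 - sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(center[1] + radius * r * cos(theta),
               center[2] + radius * r * sin(theta),
               center[3] + radius * z)
  any(point_in_zone(pts, zone))
}

#' Count putatively captured vesicles
#'
#' Applies [classify_vesicle()] to a vesicle table and reports per-cell
#' counts plus the cross-cell mean. By default only non-secretory-class
#' vesicles (the ~35-60 nm diameter class) are counted when a `class` column
#' is present.
#'
#' @param vesicles data frame with columns `x_nm`, `y_nm`, `z_nm`,
#'   `radius_nm`, and optionally `cell_id` and `class`.
#' @param zone a single [build_capture_zone()] or a named list of zones
#'   keyed by `cell_id`.
#' @param classes vesicle classes to count (`NULL` counts all).
#' @return list with `per_cell` (tibble: `cell_id`, `n_captured`) and
#'   `mean_captured`.
#' @export
count_captured <- function(vesicles, zone, classes = "non-secretory") {
  if (!nrow(vesicles)) {
    return(list(per_cell = tibble::tibble(cell_id = character(0),
                                          n_captured = integer(0)),
                mean_captured = 0))
  }
  if (is.null(vesicles$cell_id)) vesicles$cell_id <- "cell1"
  if (!is.null(classes) && !is.null(vesicles$class))
    vesicles <- vesicles[vesicles$class %in% classes, , drop = FALSE]
  per <- lapply(split(vesicles, vesicles$cell_id), function(vc) {
    zn <- if (inherits(zone, "capture_zone")) zone else zone[[vc$cell_id[1]]]
    hits <- vapply(seq_len(nrow(vc)), function(j) {
      classify_vesicle(c(vc$x_nm[j], vc$y_nm[j], vc$z_nm[j]), vc$radius_nm[j], zn)
    }, logical(1))
    tibble::tibble(cell_id = vc$cell_id[1], n_captured = sum(hits))
  })
  per <- do.call(rbind, per)
  list(per_cell = per, mean_captured = mean(per$n_captured))
}

#' Simple cortex constructors
#'
#' `make_line_cortex()` returns a straight membrane segment along x;
#' `make_arc_cortex()` a circular arc (radius of curvature `radius_nm`)
#' curving away from the cytoplasm, neck at the apex. Both declare the
#' cytoplasm on the +y side.
#'
#' @param length_nm,span_nm total arc length of the polyline, nm.
#' @param radius_nm radius of curvature of the arc, nm.
#' @param n_points number of polyline vertices.
#' @return a [cortex_model()].
#' @export
make_line_cortex <- function(length_nm = 1000, n_points = 2) {
  x <- seq(-length_nm / 2, length_nm / 2, length.out = n_points)
  cortex_model(cbind(x, 0, 0), cytoplasm_direction = c(0, 1, 0))
}

#' @rdname make_line_cortex
#' @export
make_arc_cortex <- function(radius_nm = 2000, span_nm = 1400, n_points = 41) {
  a <- seq(-span_nm / (2 * radius_nm), span_nm / (2 * radius_nm),
           length.out = n_points)
  pts <- cbind(radius_nm * sin(a), radius_nm * (1 - cos(a)), 0)
  cortex_model(pts, cytoplasm_direction = c(0, 1, 0))
}

#' Read and write vesicle model tables
#'
#' CSV columns: `cell_id` (optional), `x_nm`, `y_nm`, `z_nm`, `radius_nm`,
#' `class`. `read_cortex_csv()` reads a polyline table with columns `x_nm`,
#' `y_nm`, `z_nm` in cortex order (e.g. exported from tomogram model point
#' lists).
#'
#' @param vesicles vesicle tibble.
#' @param path CSV path.
#' @param cytoplasm_direction,neck_arclength passed to [cortex_model()].
#' @export
write_vesicles_csv <- function(vesicles, path) {
  write.csv(vesicles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vesicles_csv
#' @export
read_vesicles_csv <- function(path) {
  tibble::as_tibble(read.csv(path))
}

#' @rdname write_vesicles_csv
#' @export
read_cortex_csv <- function(path, cytoplasm_direction = NULL,
                            neck_arclength = NULL) {
  df <- read.csv(path)
  cortex_model(cbind(df$x_nm, df$y_nm, df$z_nm),
               cytoplasm_direction = cytoplasm_direction,
               neck_arclength = neck_arclength)
}
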