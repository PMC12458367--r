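test_that("zone depth is the sum of the linker lengths", {
  expect_identical(zone_depth(48, 58), 106)
  expect_identical(zone_depth(0, 0), 0)
  expect_identical(zone_depth(48, 35), 83)
  expect_identical(zone_depth(48, 58), zone_depth(58, 48))  # symmetric
  expect_error(zone_depth(-1, 10), ">= 0")
})

test_that("a straight cortex yields the expected slab geometry", {
  zone <- build_capture_zone(make_line_cortex(1000), depth = 106, arc = 200)
  # interior of the 400 nm x 106 nm slab (x lamella thickness in z)
  expect_true(all(point_in_zone(rbind(
    c(0, 50, 0), c(150, 100, 20), c(-199, 1, -80), c(0, 0, 0),  # on membrane
    c(0, 106, 0)), zone)))                                      # at full depth
  expect_false(point_in_zone(c(0, 106.001, 0), zone))   # beyond depth
  expect_false(point_in_zone(c(0, -1e-6, 0), zone))     # wrong side
  expect_false(point_in_zone(c(320, 5, 0), zone))       # beyond the arc + depth
})

test_that("zone construction demands an explicit cytoplasm side and arc span", {
  cx <- cortex_model(rbind(c(-500, 0, 0), c(500, 0, 0)))
  expect_error(build_capture_zone(cx, 106), "ambiguous normal")
  short <- make_line_cortex(300)
  expect_error(build_capture_zone(short, 106, arc = 200), "too short")
})

test_that("membership matches a dense point search along a curved cortex", {
  cx <- make_arc_cortex(radius_nm = 1000, span_nm = pi / 2 * 1000,
                        n_points = 61)  # quarter circle
  zone <- build_capture_zone(cx, depth = 106, arc = 200)
  # brute-force oracle: densely sample the truncated cortex segment and ask
  # whether any sampled membrane point's cytoplasm-side half-ball holds p
  seg <- zone$segment
  dense <- do.call(rbind, lapply(seq_len(nrow(seg) - 1), function(i) {
    tt <- seq(0, 1, length.out = 200)
    cbind(seg[i, 1] + tt * (seg[i + 1, 1] - seg[i, 1]),
          seg[i, 2] + tt * (seg[i + 1, 2] - seg[i, 2]),
          seg[i, 3] + tt * (seg[i + 1, 3] - seg[i, 3]))
  }))
  denseN <- as.vector(dense %*% zone$normal)
  oracle <- function(p, slack) {
    d <- sqrt(colSums((t(dense) - p)^2))
    h <- sum(p * zone$normal) - denseN
    any(d <= zone$depth + slack & h >= -slack)
  }
  set.seed(1)
  pts <- cbind(runif(3000, -400, 400), runif(3000, -50, 250),
               runif(3000, -150, 150))
  got <- point_in_zone(pts, zone)
  strict <- apply(pts, 1, oracle, slack = -0.5)  # clearly inside
  loose <- apply(pts, 1, oracle, slack = 0.5)    # not clearly outside
  clear <- strict == loose                       # away from the boundary
  expect_gt(mean(clear), 0.95)
  expect_identical(got[clear], strict[clear])
})

test_that("vesicle classification agrees with the surface-sampling oracle", {
  for (cx in list(make_line_cortex(1200), make_arc_cortex())) {
    zone <- build_capture_zone(cx, zone_depth(48, 58))
    set.seed(7)
    for (i in 1:50) {
      cen <- c(runif(1, -450, 450), runif(1, -80, 300), runif(1, -120, 120))
      r <- runif(1, 17.5, 30)
      expect_identical(classify_vesicle(cen, r, zone),
                       classify_vesicle_sampled(cen, r, zone))
    }
  }
})

test_that("tangency counts as captured and monotonicity holds", {
  zone <- build_capture_zone(make_line_cortex(1000), 106)
  expect_true(classify_vesicle(c(0, 106 + 25, 0), 25, zone))   # exact tangency
  expect_false(classify_vesicle(c(0, 106 + 25.01, 0), 25, zone))
  expect_true(classify_vesicle(c(0, 50, 0), 20, zone))         # center inside

  # enlarging depth or arc never loses a capture
  set.seed(3)
  cens <- cbind(runif(40, -400, 400), runif(40, 0, 250), runif(40, -100, 100))
  small <- build_capture_zone(make_line_cortex(1200), 80, arc = 150)
  deep <- build_capture_zone(make_line_cortex(1200), 130, arc = 150)
  wide <- build_capture_zone(make_line_cortex(1200), 80, arc = 250)
  for (j in seq_len(nrow(cens))) {
    if (classify_vesicle(cens[j, ], 25, small)) {
      expect_true(classify_vesicle(cens[j, ], 25, deep))
      expect_true(classify_vesicle(cens[j, ], 25, wide))
    }
  }
})

test_that("captured counts aggregate per cell with a class filter", {
  zone <- build_capture_zone(make_line_cortex(1000), 106)
  ves <- tibble::tibble(
    cell_id = c("a", "a", "a", "b", "b", "c"),
    x_nm = c(0, 10, 900, 0, 50, 0),
    y_nm = c(50, 80, 50, 60, 90, 400),
    z_nm = 0,
    radius_nm = c(25, 20, 25, 30, 18, 25),
    class = c("non-secretory", "non-secretory", "non-secretory",
              "non-secretory", "secretory", "non-secretory")
  )
  res <- count_captured(ves, zone)
  expect_equal(res$per_cell$n_captured[res$per_cell$cell_id == "a"], 2L)
  expect_equal(res$per_cell$n_captured[res$per_cell$cell_id == "b"], 1L)
  expect_equal(res$per_cell$n_captured[res$per_cell$cell_id == "c"], 0L)
  expect_equal(res$mean_captured, 1)      # counts {2, 1, 0} -> mean 1
  # counting all classes picks up the secretory vesicle in cell b
  res_all <- count_captured(ves, zone, classes = NULL)
  expect_equal(res_all$per_cell$n_captured[res_all$per_cell$cell_id == "b"], 2L)
  empty <- count_captured(ves[0, ], zone)
  expect_equal(nrow(empty$per_cell), 0)
  expect_equal(empty$mean_captured, 0)
})
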