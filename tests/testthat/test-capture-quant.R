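test_that("threshold ladder is increasing, named, and contrast-adaptive", {
  x <- const_array(10, c(8, 8, 4))
  x[4, 4, 2] <- 100
  ladder <- generate_threshold_options(x)
  expect_named(ladder, c("Basement", "Lower", "Middle", "Upper"))
  expect_true(all(diff(unclass(ladder)) > 0))
  expect_equal(which.min(ladder), c(Basement = 1L))
  # every level isolates the single bright voxel
  for (lev in names(ladder)) {
    m <- build_mask(x, ladder[[lev]])
    expect_equal(which(m), which(x == 100))
  }
})

test_that("two-population ROI puts 'Lower' between background and signal", {
  x <- array(10, c(10, 10, 2))
  sig <- sample(length(x), 40)  # 20% signal voxels
  x[sig] <- 100
  ladder <- generate_threshold_options(x)
  expect_gt(ladder[["Lower"]], 10)
  expect_lt(ladder[["Lower"]], 100)
  # mask at Lower equals the signal population, voxel by voxel
  m <- build_mask(x, ladder[["Lower"]])
  expect_identical(as.vector(m), as.vector(x == 100))
})

test_that("constant channels have no contrast", {
  expect_error(generate_threshold_options(const_array(5)), "no contrast")
})

test_that("build_mask thresholds per voxel with an inclusive comparator", {
  x <- const_array(3, c(4, 4, 2))
  roi <- array(TRUE, dim(x))
  expect_identical(build_mask(x, 0, roi), roi)           # cutoff 0 -> ROI
  expect_false(any(build_mask(x, max(x) + 1, roi)))      # above max -> empty
  expect_true(all(build_mask(x, 3, roi)))                # inclusive at cutoff

  # hand-enumerated 4 x 4 x 2 grid, cutoff 50
  vals <- array(0, c(4, 4, 2))
  vals[1, 1, 1] <- 50; vals[2, 3, 1] <- 49; vals[4, 4, 1] <- 120
  vals[3, 2, 2] <- 51; vals[1, 4, 2] <- 50; vals[2, 2, 2] <- 7
  m <- build_mask(vals, 50)
  expected_idx <- sort(c(
    which(vals == 50), which(vals == 51), which(vals == 120)))
  expect_equal(sort(which(m)), expected_idx)
  expect_equal(sum(m), 4L)
})

test_that("mask subtraction and removed fraction follow voxel counts", {
  septin <- array(FALSE, c(10, 10, 1)); septin[1:10, 1:10, 1] <- TRUE
  none <- array(FALSE, dim(septin))
  ms <- subtract_mask(septin, none)
  expect_identical(ms$modified_mask, septin)
  expect_equal(ms$removed_fraction, 0)

  ms2 <- subtract_mask(septin, septin)  # golgi covers septin entirely
  expect_false(any(ms2$modified_mask))
  expect_equal(ms2$removed_fraction, 1)

  golgi <- array(FALSE, dim(septin)); golgi[1:4, 1:10, 1] <- TRUE  # 40 of 100
  ms3 <- subtract_mask(septin, golgi)
  expect_equal(ms3$removed_fraction, 0.40)
  expect_true(all(which(ms3$modified_mask) %in% which(septin)))

  expect_error(subtract_mask(none, golgi), "no septin signal")
})

test_that("the 65% QC boundary is strict", {
  expect_true(qc_cell(0.64))
  expect_false(qc_cell(0.65))
  expect_false(qc_cell(0.66))
  expect_true(qc_cell(0))
  expect_error(qc_cell(1.2), "\\[0, 1\\]")
  expect_error(qc_cell(-0.1), "\\[0, 1\\]")
})

test_that("capture fraction hits its closed-form extremes", {
  d <- c(6, 6, 2)
  red <- array(0, d); red[1:3, , ] <- 10          # septin mask = left half
  green <- array(0, d); green[5:6, , ] <- 4       # all green outside it
  blue <- array(0, d)
  stk <- toy_stack(red, green, blue)
  res <- quantify_overlap(stk, red_level = 5, blue_level = 1e6)
  expect_equal(res$capture_fraction, 0)

  # modified mask covering the ROI -> fraction 1
  red2 <- array(10, d); green2 <- array(2, d)
  res2 <- quantify_overlap(toy_stack(red2, green2, blue),
                           red_level = 5, blue_level = 1e6)
  expect_equal(res2$capture_fraction, 1)
  expect_true(res2$capture_fraction <= 1)

  expect_error(quantify_overlap(toy_stack(red, array(0, d), blue),
                                red_level = 5, blue_level = 1e6),
               "empty green")
})

test_that("per-slice sums equal whole-volume sums", {
  sc <- generate_capture_scene(scene_config(rng_seed = 21))
  green <- sc$stack$voxels[, , , "green"]
  red <- sc$stack$voxels[, , , "red"]
  ladder <- generate_threshold_options(red)
  mask <- build_mask(red, ladder[["Lower"]])
  slicewise <- sum(vapply(seq_len(dim(green)[3]), function(z)
    sum(green[, , z][mask[, , z]]), numeric(1)))
  expect_identical(slicewise, as.numeric(sum(green[mask])))
})

test_that("enlarging the Golgi mask never increases the capture fraction", {
  sc <- generate_capture_scene(scene_config(capture_fraction = 0.1,
                                            rng_seed = 13))
  blue <- sc$stack$voxels[, , , "blue"]
  ladder <- generate_threshold_options(blue)
  cuts <- sort(c(unclass(ladder), ladder[["Basement"]] / 2), decreasing = TRUE)
  fracs <- vapply(cuts, function(cut)
    quantify_overlap(sc$stack, blue_level = cut)$capture_fraction, numeric(1))
  # decreasing cutoff = growing Golgi mask; fractions must not increase
  expect_true(all(diff(fracs) <= 1e-12))
  expect_true(all(fracs >= 0 & fracs <= 1))
})
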