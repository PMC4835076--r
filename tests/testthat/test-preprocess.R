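test_that("bias correction is near-identity on unbiased input and removes linear bias", {
  sp <- small_phantom_spec(cord_length_mm = 27, voxel_mm = 0.9)
  ph <- make_phantom(sp)
  out <- correct_bias(ph$volume, 2)
  expect_lt(max(abs(out$grid - ph$volume$grid) / pmax(ph$volume$grid, 1)), 0.01)

  spb <- small_phantom_spec(cord_length_mm = 27, voxel_mm = 0.9,
                            bias_amplitude = 0.2)
  phb <- make_phantom(spb)
  resid <- function(v) {
    x <- v$grid[phb$mask$grid]
    (max(x) - min(x)) / mean(x)
  }
  corrected <- correct_bias(phb$volume, 2)
  expect_lt(resid(corrected), resid(phb$volume) / 2)
  expect_equal(mean(corrected$grid), mean(phb$volume$grid))
})

test_that("poly_order = 0 leaves intensity ratios unchanged", {
  sp <- small_phantom_spec(cord_length_mm = 9, voxel_mm = 0.9)
  ph <- make_phantom(sp)
  out <- correct_bias(ph$volume, 0L)
  r0 <- ph$volume$grid / ph$volume$grid[1L]
  r1 <- out$grid / out$grid[1L]
  expect_equal(r1, r0)
  expect_error(correct_bias(cord_volume(array(0, c(4, 4, 4)), 1), 1),
               "all-zero")
})

test_that("crop_and_resample conserves length and preserves constants", {
  v <- cord_volume(array(rnorm(20 * 20 * 150), c(20, 20, 150)), 0.9)
  lm <- landmark_pair(superior = c(0, 0, 149), inferior = c(0, 0, 0))
  out <- crop_and_resample(v, lm, 0.3, margin_mm = Inf)
  expect_equal(dim(out$grid)[3L], 450L)
  expect_equal(dim(out$grid)[1:2], c(60L, 60L))

  cv <- cord_volume(array(7, c(10, 10, 20)), 0.9)
  oc <- crop_and_resample(cv, landmark_pair(c(0, 0, 19), c(0, 0, 0)), 0.3, Inf)
  expect_true(all(abs(oc$grid - 7) < 1e-12))
  # overshoot is clamped to the input range
  expect_gte(min(out$grid), min(v$grid))
  expect_lte(max(out$grid), max(v$grid))
})

test_that("landmark order is enforced and cropping is idempotent", {
  expect_error(landmark_pair(c(0, 0, 3), c(0, 0, 10)), "superior")
  v <- cord_volume(array(rnorm(30 * 30 * 40), c(30, 30, 40)), 0.3)
  lm <- landmark_pair(c(0, 0, 39), c(0, 0, 0))
  once <- crop_and_resample(v, lm, 0.3, margin_mm = 4)
  lm2 <- landmark_pair(c(0, 0, dim(once$grid)[3L] - 1L), c(0, 0, 0))
  twice <- crop_and_resample(once, lm2, 0.3, margin_mm = 4)
  expect_equal(twice$grid, once$grid)
})

test_that("resampling to 0.3 mm reduces mask-derived CSA error (refinement)", {
  # segment an acquisition-resolution phantom directly vs after resampling
  sp <- small_phantom_spec(cord_length_mm = 13.5, voxel_mm = 0.9, fov_mm = 27)
  ph <- make_phantom(sp)
  gt <- ph$ground_truth$csa_mm2
  seg09 <- segment_dtbm(ph$volume)
  err09 <- median(abs(cross_sectional_areas(seg09) - gt) / gt)
  lm <- landmark_pair(c(0, 0, n_slices(ph$volume) - 1L), c(0, 0, 0))
  fine <- crop_and_resample(ph$volume, lm, 0.3, margin_mm = Inf)
  seg03 <- segment_dtbm(fine)
  csa03 <- cross_sectional_areas(seg03)
  gt_fine <- approx(seq_along(gt), gt, xout = seq(1, length(gt),
                                                 length.out = length(csa03)))$y
  err03 <- median(abs(csa03 - gt_fine) / gt_fine)
  expect_lt(err03, err09)
})

test_that("landmark JSON sidecars round-trip", {
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(list(superior = c(5, 6, 40), inferior = c(5, 6, 2)),
                       tf, auto_unbox = FALSE)
  lm <- read_landmarks(tf)
  expect_equal(lm$superior, c(5L, 6L, 40L))
  expect_equal(lm$inferior, c(5L, 6L, 2L))
})
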