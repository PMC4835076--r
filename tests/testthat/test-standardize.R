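test_that("straightening is identity on a straight cord and centers a bowed one", {
  straight <- make_phantom(tube_spec(a = 3, b = 4, n_slices = 8),
                           render_volume = FALSE)
  st <- straighten(straight$mask)
  expect_identical(st$mask$grid, straight$mask$grid)
  expect_true(all(st$shifts == 0L))

  bowed <- make_phantom(small_phantom_spec(centerline_amplitude_mm = 6),
                        render_volume = FALSE)
  st2 <- straighten(bowed$mask)
  d <- dim(st2$mask$grid)
  ctr_mm <- (c(d[1L], d[2L]) - 1) / 2 * 0.3
  for (z in c(1L, 15L, 30L, 45L, 60L)) {
    com <- cordmorph:::slice_com(st2$mask$grid[, , z])
    expect_lt(max(abs((com - 1) * 0.3 - ctr_mm)), 0.3 + 1e-9)
  }
  # per-slice areas exactly preserved
  expect_identical(cordmorph:::slice_counts(st2$mask),
                   cordmorph:::slice_counts(bowed$mask))
  # shifts equal the negated centerline rounded to voxels
  d0 <- dim(bowed$mask$grid)
  ctr_vox <- (d0[1:2] + 1) / 2
  com_vox <- cbind(st2$centerline$x_mm / 0.3 + 1, st2$centerline$y_mm / 0.3 + 1)
  expect_equal(st2$shifts,
               matrix(as.integer(round(rep(ctr_vox, each = nrow(com_vox)) - com_vox)),
                      ncol = 2L))
})

test_that("straightening refuses empty slices", {
  g <- array(FALSE, c(10, 10, 3))
  g[4:6, 4:6, c(1L, 3L)] <- TRUE
  expect_error(straighten(cord_mask(g, 0.3)), "empty")
})

test_that("length standardization is exact nearest-neighbor and idempotent", {
  tube <- make_phantom(tube_spec(a = 3, b = 4, n_slices = 20),
                       render_volume = FALSE)
  same <- standardize_length(tube$mask, 20L)
  expect_identical(same$grid, tube$mask$grid)

  sm <- standardize_length(tube$mask, 413L)
  expect_equal(dim(sm$grid)[3L], 413L)
  for (z in c(1L, 100L, 413L))
    expect_identical(sm$grid[, , z], tube$mask$grid[, , 1L])
  twice <- standardize_length(sm, 413L)
  expect_identical(twice$grid, sm$grid)
  expect_error(standardize_length(tube$mask, 1L), "L must be")
})

test_that("a linear CSA ramp survives rescaling within one slice increment", {
  # build a 90-slice mask whose per-slice square side grows linearly
  n <- 90L
  g <- array(FALSE, c(40, 40, n))
  side <- round(seq(6, 24, length.out = n))
  for (z in seq_len(n)) {
    h <- side[z] %/% 2L
    g[(20 - h):(20 + h), (20 - h):(20 + h), z] <- TRUE
  }
  m <- cord_mask(g, 0.3)
  ramp <- cross_sectional_areas(m)
  sm <- standardize_length(m, 45L)
  got <- cross_sectional_areas(sm)
  expected <- ramp[round((seq_len(45L) - 1) * (n - 1) / 44) + 1L]
  inc <- max(abs(diff(ramp)))
  expect_true(all(abs(got - expected) <= inc + 1e-9))
})

test_that("cohort standard length is the lower median", {
  expect_equal(cohort_standard_length(c(400L, 413L, 420L)), 413L)
  expect_equal(cohort_standard_length(c(7L, 7L, 7L)), 7L)
  expect_equal(cohort_standard_length(c(10L, 20L, 30L, 40L)), 20L)
  masks <- lapply(c(5L, 7L, 9L), function(nz)
    cord_mask(array(TRUE, c(3, 3, nz)), 0.3))
  expect_equal(cohort_standard_length(masks), 7L)
  expect_error(cohort_standard_length(list()), "at least one")
})

test_that("morphometry is invariant to straightening (translation only)", {
  bowed <- make_phantom(small_phantom_spec(centerline_amplitude_mm = 5),
                        render_volume = FALSE)
  st <- straighten(bowed$mask)
  expect_identical(as.numeric(cross_sectional_areas(bowed$mask)),
                   as.numeric(cross_sectional_areas(st$mask)))
  rd0 <- radial_distances(bowed$mask)
  rd1 <- radial_distances(st$mask)
  # translation is exact up to the bisection resolution of the border search
  expect_equal(unclass(rd0), unclass(rd1), tolerance = 1e-4,
               ignore_attr = TRUE)
})
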