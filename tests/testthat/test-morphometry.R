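test_that("radial distances recover circle and ellipse geometry to half a voxel", {
  circ <- make_phantom(tube_spec(a = 4, b = 4, n_slices = 2, fov_mm = 20),
                       render_volume = FALSE)
  rd <- radial_distances(circ$mask)
  expect_equal(ncol(rd), 72L)
  expect_true(all(rd >= 3.85 & rd <= 4.15))

  ell <- make_phantom(tube_spec(a = 3, b = 4, n_slices = 2, fov_mm = 20),
                      render_volume = FALSE)
  rde <- radial_distances(ell$mask)
  expect_lte(abs(rde[1L, "deg000"] - 3), 0.1501)   # anterior = A-P semi-axis
  expect_lte(abs(rde[1L, "deg180"] - 3), 0.1501)
  expect_lte(abs(rde[1L, "deg090"] - 4), 0.1501)   # lateral = R-L semi-axis
  expect_lte(abs(rde[1L, "deg270"] - 4), 0.1501)
})

test_that("ray-cast radii match the boundary-pixel oracle on random convex shapes", {
  set.seed(42)
  vox <- 0.3
  diag_tol <- vox * sqrt(2)
  n_checked <- 0L
  for (rep in 1:8) {
    sl <- random_convex_mask()
    if (is.null(sl)) next
    rd <- radial_distances(one_slice_mask(sl, vox))
    oracle <- rd_boundary_oracle(sl, vox)
    ok <- !is.na(oracle)
    expect_true(all(abs(rd[1L, ok] - oracle[ok]) <= diag_tol))
    n_checked <- n_checked + sum(ok)
  }
  expect_gt(n_checked, 300L)
})

test_that("CSA is voxel count times voxel area and guards empty slices", {
  g <- array(FALSE, c(40, 40, 2))
  idx <- arrayInd(seq_len(40 * 40), c(40, 40))
  pick <- idx[(idx[, 1L] - 20)^2 + (idx[, 2L] - 20.1)^2 <= 13.33^2, ]
  g[cbind(pick, 1L)] <- TRUE
  g[cbind(pick, 2L)] <- TRUE
  g2 <- g[, , 1L]
  expect_equal(sum(g2), 559L)        # fixture chosen to hit a known count
  m <- cord_mask(g, 0.3)
  expect_equal(as.numeric(cross_sectional_areas(m)), rep(50.31, 2L))

  circ <- make_phantom(tube_spec(a = 4, b = 4, n_slices = 2, fov_mm = 20),
                       render_volume = FALSE)
  csa <- cross_sectional_areas(circ$mask)
  expect_lt(abs(csa[1L] - pi * 16) / (pi * 16), 0.02)

  g[, , 2L] <- FALSE
  expect_error(cross_sectional_areas(cord_mask(g, 0.3)), "empty")
})

test_that("RD and CSA are exactly translation invariant and rotation permutes RD", {
  set.seed(7)
  sl <- random_convex_mask(n = 50)
  m <- one_slice_mask(sl)
  rd0 <- radial_distances(m)
  csa0 <- cross_sectional_areas(m)
  shifted <- one_slice_mask(cordmorph:::shift2(sl, 3L, -4L))
  expect_equal(unclass(radial_distances(shifted)), unclass(rd0),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(as.numeric(cross_sectional_areas(shifted)),
                   as.numeric(csa0))
  # 90 degree rotation about the slice center: RD columns shift by 18 bins
  rot <- one_slice_mask(t(sl[nrow(sl):1, ]))
  rd90 <- radial_distances(rot)
  expect_equal(as.numeric(rd90[1L, ]),
               as.numeric(rd0[1L, c(19:72, 1:18)]), tolerance = 1e-9)
  expect_identical(as.numeric(cross_sectional_areas(rot)),
                   as.numeric(csa0))
})

test_that("the polygon through (angle, radius) points reconstructs CSA within 5%", {
  ell <- make_phantom(tube_spec(a = 3.5, b = 5, n_slices = 2, fov_mm = 20),
                      render_volume = FALSE)
  rd <- radial_distances(ell$mask)[1L, ]
  th <- (seq_along(rd) - 1) * 5 * pi / 180
  x <- rd * cos(th); y <- rd * sin(th)
  nxt <- c(2:length(rd), 1L)
  poly_area <- abs(sum(x * y[nxt] - x[nxt] * y)) / 2
  csa <- as.numeric(cross_sectional_areas(ell$mask))[1L]
  expect_lt(abs(poly_area - csa) / csa, 0.05)
})

test_that("anterior-only atrophy shifts the center of mass posteriorly and
           lowers RD at both anterior and posterior angles", {
  base <- tube_spec(a = 4, b = 5, n_slices = 4, fov_mm = 24)
  atr <- atrophy_field(direction = "anterior", peak = 0.4,
                       extent = c("C2", "C7"), ramp_frac = 1e-6)
  ph0 <- make_phantom(base, render_volume = FALSE)
  ph1 <- make_phantom(base, atr, render_volume = FALSE)
  com0 <- cordmorph:::slice_com(ph0$mask$grid[, , 2L])
  com1 <- cordmorph:::slice_com(ph1$mask$grid[, , 2L])
  expect_lt(com1[2L], com0[2L])        # posterior displacement (smaller y)
  rd0 <- radial_distances(ph0$mask)[2L, ]
  rd1 <- radial_distances(ph1$mask)[2L, ]
  expect_lt(rd1["deg000"], rd0["deg000"] - 0.3)
  expect_lt(rd1["deg180"], rd0["deg180"] - 0.3)
})

test_that("vertebral level maps partition [0, L) and segment lookups follow usage", {
  map <- label_levels(413L)
  expect_equal(map$level, paste0("C", 2:7))
  widths <- map$end - map$start
  expect_true(all(widths %in% c(68L, 69L)))
  expect_equal(sum(widths), 413L)
  expect_equal(map$end[1L], 413L)
  expect_equal(map$start[6L], 0L)
  # intervals are contiguous superior -> inferior
  expect_equal(map$start[-6L], map$end[-1L])

  expect_equal(vertebral_to_segments("C4"), c("C5", "C6"))
  expect_equal(vertebral_to_segments("C3", "C6"), c("C4", "C5", "C6", "C7"))
  expect_equal(vertebral_to_segments("C4", "C7"), c("C5", "C6", "C7", "C8"))
  expect_error(label_levels(413L, boundaries = c(0.3, 0.2, 0.5, 0.6, 0.7)),
               "increasing")
})
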