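test_that("ground-truth CSA is analytic and atrophy scales the targeted axis", {
  sp <- tube_spec(a = 4, b = 4, n_slices = 6)
  ph <- make_phantom(sp, render_volume = FALSE)
  expect_equal(ph$ground_truth$csa_mm2, rep(pi * 16, 6), tolerance = 1e-4)

  atr <- atrophy_field(direction = "anterior-posterior", peak = 0.20,
                       extent = c("C2", "C7"), ramp_frac = 1e-6)
  sp2 <- small_phantom_spec()
  g0 <- make_phantom(sp2, render_volume = FALSE)$ground_truth
  g1 <- make_phantom(sp2, atr, render_volume = FALSE)$ground_truth
  mid <- which(g1$atrophy > 0.19)
  expect_gt(length(mid), 10)
  expect_equal(g1$a_ant_mm[mid], g0$a_ant_mm[mid] * (1 - g1$atrophy[mid]),
               tolerance = 1e-12)
  expect_equal(g1$b_rl_mm, g0$b_rl_mm)          # R-L untouched
  expect_equal(g1$csa_mm2, pi / 2 * (g1$a_ant_mm + g1$a_post_mm) * g1$b_rl_mm)
})

test_that("atrophy profile is zero outside its extent and bounded in [0,1)", {
  atr <- atrophy_field(peak = 0.3, extent = c("C3", "C6"))
  frac <- seq(0, 1, length.out = 413)
  p <- profile_at(atr, frac)
  expect_true(all(p >= 0 & p < 1))
  expect_true(all(p[frac < 1 / 6 - 1e-9] == 0))
  expect_true(all(p[frac > 5 / 6 + 1e-9] == 0))
  expect_equal(max(p), 0.3, tolerance = 1e-9)
  expect_equal(profile_at(NULL, frac), rep(0, 413))
})

test_that("seeded generation is bit-reproducible and oversize sections are rejected", {
  sp <- small_phantom_spec(noise_sigma = 8, bias_amplitude = 0.1, seed = 11)
  a <- make_phantom(sp); b <- make_phantom(sp)
  expect_identical(a$volume$grid, b$volume$grid)
  expect_identical(a$mask$grid, b$mask$grid)

  big <- tube_spec(a = 10, b = 14, fov_mm = 24)
  expect_error(make_phantom(big), "field of view")
})

test_that("mask voxel-count CSA converges to the analytic value as voxels shrink", {
  err_at <- function(vx) {
    sp <- phantom_spec(cord_length_mm = 6 * vx, voxel_mm = vx, fov_mm = 24,
                       centerline_amplitude_mm = 0.4)
    ph <- make_phantom(sp, render_volume = FALSE)
    mean(abs(cross_sectional_areas(ph$mask) - ph$ground_truth$csa_mm2))
  }
  errs <- vapply(c(0.9, 0.3, 0.1), err_at, numeric(1L))
  expect_true(all(diff(errs) < 0))
})

test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec(intensities = c(cord = 200, csf = 100, background = 10)),
               "csf")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(atrophy_field(peak = 1.2), "peak")
})

test_that("cohorts have the configured sizes and record schema", {
  cs <- cohort_spec(n_patients = 18, n_controls = 18, seed = 5)
  ps <- phantom_spec(cord_length_mm = 10, voxel_mm = 1, fov_mm = 28)
  man <- cordmorph:::cohort_manifest(cs, ps)
  expect_equal(nrow(man$records), 36L)
  expect_equal(sum(man$records$group == "patient"), 18L)
  need <- c("id", "group", "mmt_c5", "mmt_c6", "mmt_c7", "mmt_c8",
            "mmt_pct_c5", "mmt_pct_c8", "mmt_arm", "mmt_leg", "mmt_total",
            "mfm_d1", "mfm_d2", "mfm_d3", "alsfrs_arm", "alsfrs_leg",
            "alsfrs_total", "disease_duration_years", "age", "sex")
  expect_true(all(need %in% names(man$records)))
  pat <- man$records[man$records$group == "patient", ]
  expect_true(all(pat$mmt_c5 <= 10 & pat$mmt_c7 <= 30 & pat$mmt_c8 <= 20))
  expect_equal(pat$mmt_total, pat$mmt_arm + pat$mmt_leg)
  expect_true(all(pat$peak_atrophy > 0))
  # small cohort, volumes rendered
  co <- make_cohort(cohort_spec(n_patients = 2, n_controls = 2, seed = 2), ps)
  expect_length(co$subjects, 4L)
  expect_s3_class(co$subjects[[1L]]$volume, "cord_volume")
})

test_that("clinical_coupling = 1 gives perfect rank correlation with peak atrophy", {
  cs <- cohort_spec(n_patients = 18, n_controls = 18, clinical_coupling = 1,
                    between_subject_cv = 0.2, seed = 3)
  man <- cordmorph:::cohort_manifest(cs, phantom_spec())
  pat <- man$records[man$records$group == "patient", ]
  expect_equal(cor(pat$peak_atrophy, pat$mmt_pct_c5, method = "spearman"), 1)
  expect_equal(cor(pat$peak_atrophy, pat$mmt_pct_c8, method = "spearman"), 1)
})

test_that("clinical_coupling = 0 leaves scores independent of atrophy", {
  cs <- cohort_spec(n_patients = 100, n_controls = 2, clinical_coupling = 0,
                    between_subject_cv = 0.2, seed = 4)
  man <- cordmorph:::cohort_manifest(cs, phantom_spec())
  pat <- man$records[man$records$group == "patient", ]
  rho <- cor(pat$peak_atrophy, pat$mmt_pct_c5, method = "spearman")
  expect_lt(abs(rho), 0.2)
})
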