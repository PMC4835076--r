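test_that("identical groups give p >= 0.5 everywhere", {
  set.seed(1)
  X <- matrix(rnorm(6 * 20), 6, 20)
  map <- permutation_map(X, X, n_perm = 2000, seed = 3)
  expect_true(all(map$p >= 0.5))
  expect_equal(max(abs(map$statistic)), 0, tolerance = 1e-12)
})

test_that("permutation p matches exhaustive enumeration for 4 + 4 groups", {
  set.seed(11)
  P <- matrix(rnorm(4 * 6, 0), 4, 6)
  C <- matrix(rnorm(4 * 6, 0.8), 4, 6)
  exact <- perm_exact_oracle(P, C)
  map <- permutation_map(P, C, n_perm = 10000, seed = 5)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_true(all(abs(map$p - exact) <= 3 * se + 2 / 10000))
})

test_that("the add-one estimator floors p at 1/(n_perm + 1)", {
  set.seed(30)
  P <- matrix(rnorm(10 * 2), 10, 2)
  C <- matrix(rnorm(10 * 2, 100), 10, 2)   # total separation
  map <- permutation_map(P, C, n_perm = 1000, seed = 1)
  expect_true(all(map$p >= 1 / 1001))
  # only a resample of the true partition can reach T_obs: p sits at the floor
  big <- permutation_map(P, C, n_perm = 100000, seed = 1)
  expect_gte(min(big$p), 1 / 100001)
  expect_lte(min(big$p), 3 / 100001)
})

test_that("3D RD arrays map to matrix-shaped p maps and mismatches error", {
  P <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  C <- array(rnorm(4 * 4 * 5, 1), c(4, 4, 5))
  map <- permutation_map(P, C, n_perm = 500, seed = 2)
  expect_equal(dim(map$p), c(4L, 5L))
  expect_error(permutation_map(matrix(0, 3, 4), matrix(0, 3, 5)),
               "same sites")
  expect_warning(permutation_map(matrix(rnorm(8), 4), matrix(rnorm(8), 4),
                                 n_perm = 50, seed = 1), "coarse")
})

test_that("atrophy rate is the normalized group difference and antisymmetric", {
  P <- matrix(64, 4, 3)
  C <- matrix(80, 4, 3)
  expect_equal(as.numeric(atrophy_rate(P, C)), rep(20, 3))
  expect_equal(as.numeric(atrophy_rate(C, C)), rep(0, 3))
  set.seed(2)
  A <- matrix(rexp(4 * 6) + 1, 4)
  B <- matrix(rexp(4 * 6) + 1, 4)
  fwd <- as.numeric(atrophy_rate(A, B))          # (mB - mA)/mB
  swapped <- as.numeric(atrophy_rate(B, A))      # (mA - mB)/mA
  mA <- colMeans(A); mB <- colMeans(B)
  expect_equal(swapped, -fwd * mB / mA)
  expect_error(atrophy_rate(A, B * 0), "positive")
})

test_that("Spearman maps equal rank-then-Pearson and the exact oracle at n = 6", {
  set.seed(3)
  X <- matrix(sample(20, 6 * 10, replace = TRUE), 6, 10)  # ties included
  s <- sample(10, 6, replace = TRUE)
  cm <- correlate_profiles(X, s, exact_n_max = 6L)
  ref_rho <- apply(X, 2L, function(col) cor(rank(col), rank(s)))
  expect_equal(cm$rho, ref_rho, tolerance = 1e-12)
  expect_equal(cm$method, "exact")
  # brute-force exact p at one site
  perms <- cordmorph:::all_permutations(6L)
  for (site in c(1L, 4L)) {
    rho_null <- apply(perms, 1L, function(pm)
      cor(rank(X[, site]), rank(s)[pm]))
    expect_equal(cm$p[site], mean(abs(rho_null) >= abs(cm$rho[site]) - 1e-12))
  }
  # monotone scores -> rho = 1
  prof <- matrix(c(1, 3, 7, 2, 9, 5), 6, 2)
  cm2 <- correlate_profiles(prof, prof[, 1L]^3, exact_n_max = 6L)
  expect_equal(cm2$rho, c(1, 1))
  # constant scores flagged
  expect_warning(cm3 <- correlate_profiles(prof, rep(2, 6)), "constant")
  expect_true(all(is.na(cm3$rho)))
})

test_that("t-approximation path matches cor.test for larger n", {
  set.seed(4)
  X <- matrix(rnorm(15 * 4), 15, 4)
  s <- rnorm(15)
  cm <- correlate_profiles(X, s)
  expect_equal(cm$method, "t-approximation")
  ref <- apply(X, 2L, function(col)
    suppressWarnings(cor.test(col, s, method = "spearman")$estimate))
  expect_equal(cm$rho, unname(ref), tolerance = 1e-12)
})

test_that("gradient correlation recovers built-in slope coupling", {
  map <- label_levels(120L)
  sl <- level_slices(map, "C4", "C7")
  n <- 12L
  set.seed(5)
  slopes <- seq(-0.5, 0.5, length.out = n)
  csa <- t(vapply(slopes, function(b) 60 + b * (seq_len(120L) - 1) * 0.3,
                  numeric(120L)))
  mmt <- t(vapply(slopes, function(b) 80 + (10 * b) * (1:4), numeric(4L)))
  g <- gradient_correlation(csa, map, mmt)
  expect_equal(g$rho, 1)
  # analytic slope of an exact line
  expect_equal(g$slope_csa, slopes, tolerance = 1e-9)
  # constant slopes -> undefined, reported as NA
  csa0 <- matrix(60, n, 120L)
  mmt0 <- matrix(80, n, 4L)
  g0 <- gradient_correlation(csa0, map, mmt0)
  expect_true(is.na(g0$rho))
})

test_that("proximal-distal Wilcoxon handles ties, zeros and matches the 2^n oracle", {
  expect_equal(proximal_distal_test(c(70, 80, 90), c(70, 80, 90))$p, 1)
  expect_true(proximal_distal_test(c(1, 2), c(1, 2))$all_tied)
  set.seed(6)
  d5 <- round(rnorm(8, 70, 10)); d8 <- round(rnorm(8, 65, 10))
  r <- proximal_distal_test(d5, d8)
  expect_equal(r$p, signed_rank_oracle(d5 - d8), tolerance = 1e-12)
  expect_equal(r$method, "exact")
  # antisymmetric pairs: statistic at the distribution center
  d <- c(3, -3, 5, -5, 7, -7, 9, -9)
  rs <- proximal_distal_test(d, rep(0, 8))
  expect_equal(rs$statistic, 8 * 9 / 4)
  expect_gt(rs$p, 0.9)
})

test_that("table1 summarises the cohort with missing-value accounting", {
  cs <- cohort_spec(n_patients = 6, n_controls = 6, seed = 8)
  man <- cordmorph:::cohort_manifest(cs, phantom_spec())
  t1 <- table1_summary(man$records)
  expect_equal(t1$patients_mean[t1$characteristic == "n"], 6)
  pct <- t1[t1$characteristic == "mmt_pct_c5", ]
  pat <- man$records[man$records$group == "patient", ]
  expect_equal(pct$patients_mean, mean(pat$mmt_pct_c5))
  # raw scores are the rounded percent-of-maximum: 7/10 <-> 70%
  expect_true(all(abs(pat$mmt_pct_c5 - 10 * pat$mmt_c5) <= 5))
  expect_true(all(abs(pat$mmt_pct_c8 - 5 * pat$mmt_c8) <= 2.5))
  mfm <- t1[t1$characteristic == "mfm_d1", ]
  expect_equal(mfm$controls_missing, 6L)
  expect_true(is.nan(mfm$controls_mean) || is.na(mfm$controls_mean))
})
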