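# Clinical statistics: Spearman correlation maps, gradient correlation,
# paired proximal-vs-distal strength test, and the cohort summary table.

# all permutations of 1..n as an n! x n matrix (n <= 8 in practice)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- ((k - 1L) * nrow(sub) + 1L):(k * nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, 2:n] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

std_ranks <- function(x) {
  r <- rank(x)           # average ranks for ties
  r - mean(r)
}

# Spearman rho (rank-then-Pearson, average ranks for ties) with p-value:
# exact full enumeration of score-rank permutations for n <= exact_n_max,
# t approximation otherwise. Returns c(rho, p); rho is NA for constant input.
spearman_test <- function(x, y, exact_n_max = 8L, two_sided = TRUE) {
  n <- length(x)
  rx <- std_ranks(x); ry <- std_ranks(y)
  sx <- sqrt(sum(rx^2)); sy <- sqrt(sum(ry^2))
  if (sx == 0 || sy == 0) return(c(rho = NA_real_, p = NA_real_))
  rho <- sum(rx * ry) / (sx * sy)
  if (n <= exact_n_max) {
    perms <- all_permutations(n)
    rho_null <- (matrix(rx[perms], nrow(perms), n) %*% ry) / (sx * sy)
    p <- if (two_sided) mean(abs(rho_null) >= abs(rho) - 1e-12)
         else mean(rho_null >= rho - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- if (two_sided) 2 * pt(-abs(tstat), n - 2) else pt(-tstat, n - 2)
    p <- min(p, 1)
  }
  c(rho = rho, p = p)
}

#' Site-wise Spearman correlation between profiles and a clinical score
#'
#' Spearman's rank correlation (average-rank tie handling) between a clinical
#' score and the profile value at every site. P-values come from the exact
#' permutation distribution of the score ranks when `n <= exact_n_max`
#' (enumeration, shared across sites) and from the t approximation otherwise;
#' the map is thresholded at the supra-significance level `alpha`.
#'
#' @param profiles subjects x sites matrix (CSA: sites = L; RD: flattened
#'   L x 72 with attribute `rd_dim`, as produced by [cohort_profiles()]).
#' @param scores numeric clinical score, one value per subject; a constant
#'   vector leaves every site flagged (`rho` undefined).
#' @param alpha supra-significance level (default 1e-3).
#' @param exact_n_max largest n for exact enumeration.
#' @param two_sided use the two-sided p-value (default).
#' @return A `correlation_map`: list with `rho`, `p`, `significant`, `alpha`,
#'   `n`, `method`.
#' @export
correlate_profiles <- function(profiles, scores, alpha = 1e-3,
                               exact_n_max = 8L, two_sided = TRUE) {
  X <- as.matrix(profiles)
  n <- nrow(X)
  if (n < 4L) stop("need >= 4 subjects with scores")
  if (length(scores) != n) stop("one score per subject required")
  keep <- is.finite(scores)
  if (!all(keep)) { X <- X[keep, , drop = FALSE]; scores <- scores[keep]; n <- sum(keep) }
  if (n < 4L) stop("need >= 4 subjects with non-missing scores")
  ry <- std_ranks(scores)
  sy <- sqrt(sum(ry^2))
  if (sy == 0) {
    warning("constant score vector: rho undefined at every site")
    out <- list(rho = rep(NA_real_, ncol(X)), p = rep(NA_real_, ncol(X)),
                significant = rep(FALSE, ncol(X)), alpha = alpha, n = n,
                method = "undefined")
    class(out) <- "correlation_map"
    return(out)
  }
  R <- apply(X, 2L, rank)                    # ranks per site
  R <- sweep(R, 2L, colMeans(R))
  sx <- sqrt(colSums(R^2))
  const <- sx == 0
  sx[const] <- 1
  rho <- as.numeric(crossprod(R, ry)) / (sx * sy)
  rho[const] <- NA_real_
  if (n <= exact_n_max) {
    method <- "exact"
    perms <- all_permutations(n)
    yperm <- matrix(ry[perms], nrow(perms), n)   # permuted score ranks
    null_num <- yperm %*% R                      # n! x sites
    null_rho <- sweep(null_num, 2L, sx * sy, "/")
    p <- if (two_sided)
      colMeans(abs(null_rho) >= rep(abs(rho) - 1e-12, each = nrow(perms)))
    else colMeans(null_rho >= rep(rho - 1e-12, each = nrow(perms)))
  } else {
    method <- "t-approximation"
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
    p <- if (two_sided) 2 * pt(-abs(tstat), n - 2) else pt(-tstat, n - 2)
    p <- pmin(p, 1)
  }
  p[const] <- NA_real_
  sig <- !is.na(p) & p < alpha
  structure(list(rho = rho, p = p, significant = sig, alpha = alpha, n = n,
                 method = method),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d sites, n = %d (%s)\n",
              length(x$rho), x$n, x$method))
  cat(sprintf("  %d sites significant at alpha = %g\n",
              sum(x$significant), x$alpha))
  invisible(x)
}

ols_slope <- function(x, Y) {
  # slope of each row of Y on x
  xc <- x - mean(x)
  as.numeric(Y %*% xc) / sum(xc^2)
}

#' Correlation between rostro-caudal CSA gradient and MMT gradient
#'
#' Per subject, the CSA gradient is the least-squares slope of CSA over the
#' slices spanning the C4-C7 vertebral levels (x in mm along the cord), and
#' the MMT gradient is the least-squares slope of the percent-of-maximum
#' subscores over spinal levels C5..C8 (x = 1..4). The two slopes are then
#' correlated across subjects with Spearman's rank correlation.
#'
#' @param csa subjects x L CSA matrix.
#' @param levels a [label_levels()] map covering C4-C7.
#' @param mmt_pct subjects x 4 matrix of MMT percent scores (C5..C8).
#' @param voxel_mm slice thickness of the standardized grid (mm).
#' @param exact_n_max passed to the Spearman test.
#' @return List with `rho`, `p`, `slope_csa`, `slope_mmt`; `rho` is `NA`
#'   (reported as undefined) when either slope vector is constant.
#' @export
gradient_correlation <- function(csa, levels, mmt_pct, voxel_mm = 0.3,
                                 exact_n_max = 8L) {
  csa <- as.matrix(csa); mmt_pct <- as.matrix(mmt_pct)
  if (nrow(csa) < 4L) stop("need >= 4 subjects")
  if (nrow(mmt_pct) != nrow(csa) || ncol(mmt_pct) != 4L)
    stop("mmt_pct must be subjects x 4 (C5..C8)")
  sl <- level_slices(levels, "C4", "C7")
  x_mm <- sl * voxel_mm
  slope_csa <- ols_slope(x_mm, csa[, sl + 1L, drop = FALSE])
  slope_mmt <- ols_slope(1:4, mmt_pct)
  st <- spearman_test(slope_csa, slope_mmt, exact_n_max = exact_n_max)
  list(rho = unname(st[1L]), p = unname(st[2L]),
       slope_csa = slope_csa, slope_mmt = slope_mmt)
}

#' Wilcoxon signed-rank test of proximal vs distal strength
#'
#' Two-sided paired test on percent-of-maximum MMT scores at the proximal
#' (C5) and distal (C8) spinal levels. Zero differences are dropped; with
#' `n <= exact_n_max` non-zero pairs the exact sign-flip distribution of the
#' signed-rank statistic is used (tie-aware, computed by dynamic
#' programming), otherwise a normal approximation with tie correction.
#'
#' @param c5_pct,c8_pct paired percent scores.
#' @param exact_n_max largest number of non-zero pairs for the exact
#'   distribution (default 25).
#' @return List with `statistic` (V, sum of positive-difference ranks), `p`,
#'   `n_nonzero`, `method`, and `all_tied` (TRUE when every pair was tied;
#'   then `p = 1` by convention).
#' @export
proximal_distal_test <- function(c5_pct, c8_pct, exact_n_max = 25L) {
  if (length(c5_pct) != length(c8_pct)) stop("paired scores required")
  d <- c5_pct - c8_pct
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p = 1, n_nonzero = 0L, method = "degenerate",
                all_tied = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_n_max) {
    # exact distribution of V over all 2^n sign assignments via generating
    # function; average ranks are half-integers so work on 2*rank
    w <- as.integer(round(2 * r))
    S <- sum(w)
    f <- numeric(S + 1L); f[1L] <- 1
    for (wi in w) f <- f + c(rep(0, wi), f[seq_len(S + 1L - wi)])
    f <- f / 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(f[seq_len(v2 + 1L)])
    p_ge <- sum(f[(v2 + 1L):(S + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(statistic = V, p = p, n_nonzero = n, method = method, all_tied = FALSE)
}

#' Cohort summary table (demographics and clinical features)
#'
#' Mean and SD per group for age, disease duration, MMT raw and
#' percent-of-maximum subscores, MFM domains and ALSFRS-R subscores.
#' Missing fields are reported as `NA` with a missing count.
#'
#' @param cohort a `cord_cohort` or its `records` data frame.
#' @return Data frame with columns `characteristic`, `patients_mean`,
#'   `patients_sd`, `controls_mean`, `controls_sd`, `patients_missing`,
#'   `controls_missing`.
#' @export
table1_summary <- function(cohort) {
  rec <- if (inherits(cohort, "cord_cohort")) cohort$records else cohort
  stopifnot(is.data.frame(rec), "group" %in% names(rec))
  rows <- c(age = "age", disease_duration_years = "disease_duration_years",
            mmt_arm = "mmt_arm", mmt_leg = "mmt_leg", mmt_total = "mmt_total",
            mmt_c5 = "mmt_c5", mmt_c6 = "mmt_c6", mmt_c7 = "mmt_c7",
            mmt_c8 = "mmt_c8",
            mmt_pct_c5 = "mmt_pct_c5", mmt_pct_c6 = "mmt_pct_c6",
            mmt_pct_c7 = "mmt_pct_c7", mmt_pct_c8 = "mmt_pct_c8",
            mfm_d1 = "mfm_d1", mfm_d2 = "mfm_d2", mfm_d3 = "mfm_d3",
            alsfrs_arm = "alsfrs_arm", alsfrs_leg = "alsfrs_leg",
            alsfrs_total = "alsfrs_total")
  pat <- rec[rec$group == "patient", , drop = FALSE]
  ctl <- rec[rec$group == "control", , drop = FALSE]
  summ <- function(df, f) {
    if (!f %in% names(df)) return(c(NA_real_, NA_real_, nrow(df)))
    v <- df[[f]]
    c(mean(v, na.rm = TRUE), sd(v, na.rm = TRUE), sum(is.na(v)))
  }
  out <- data.frame(characteristic = c("n", names(rows)),
                    patients_mean = NA_real_, patients_sd = NA_real_,
                    controls_mean = NA_real_, controls_sd = NA_real_,
                    patients_missing = 0L, controls_missing = 0L)
  out[1L, 2:5] <- c(nrow(pat), NA, nrow(ctl), NA)
  for (i in seq_along(rows)) {
    sp <- summ(pat, rows[[i]]); sc <- summ(ctl, rows[[i]])
    out[i + 1L, 2:7] <- c(sp[1L], sp[2L], sc[1L], sc[2L], sp[3L], sc[3L])
  }
  out
}
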