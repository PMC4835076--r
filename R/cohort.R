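# Cohort generation: per-subject geometric variability, patient-only atrophy,
# and clinical scores with configurable coupling to atrophy severity.

# Patient clinical score parameters: manual muscle testing percent-of-maximum
# means/SDs per spinal level, functional scales, demographics. Controls are
# healthy (full strength); functional scales are not administered to them.
CLINICAL_DEFAULTS <- list(
  mmt_pct_mean = c(c5 = 73.3, c6 = 84.4, c7 = 86.9, c8 = 72.2),
  mmt_pct_sd   = c(c5 = 19.4, c6 = 18.9, c7 = 15.2, c8 = 13.5),
  mmt_max      = c(c5 = 10, c6 = 10, c7 = 30, c8 = 20),
  mmt_leg      = c(mean = 46.7, sd = 15.2, max = 70),
  mfm_mean     = c(d1 = 19.5, d2 = 37.4, d3 = 38.3),
  mfm_sd       = c(d1 = 11.1, d2 = 1.6, d3 = 1.5),
  alsfrs_arm   = c(mean = 7.1, sd = 1.2, max = 8),
  alsfrs_leg   = c(mean = 3.3, sd = 1.4, max = 8),
  alsfrs_other = c(mean = 29.8, sd = 3.0, max = 32),
  duration     = c(mean = 26, sd = 15),
  age          = c(patient = 36, control = 35, sd = 11),
  male_frac    = c(patient = 10 / 18, control = 11 / 18)
)

#' Cohort specification
#'
#' @param n_patients,n_controls group sizes (both must be >= 2).
#' @param atrophy an [atrophy_field] applied to patients (subject peaks are
#'   jittered), or `NULL` for a null cohort.
#' @param between_subject_cv coefficient of variation of ellipse semi-axes
#'   (and of the atrophy peak) across subjects; lognormal, mean-one.
#' @param clinical_coupling correlation in `[-1, 1]` between a patient's
#'   realized peak atrophy and the latent scale of their MMT percent scores.
#'   0 (the default) generates scores independent of atrophy.
#' @param seed RNG seed for the whole cohort.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 18L, n_controls = 18L,
                        atrophy = atrophy_field(),
                        between_subject_cv = 0.05,
                        clinical_coupling = 0,
                        seed = 1L) {
  if (n_patients < 2L || n_controls < 2L) stop("group sizes must be >= 2")
  if (abs(clinical_coupling) > 1) stop("clinical_coupling must be in [-1, 1]")
  if (between_subject_cv < 0) stop("between_subject_cv must be >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 atrophy = atrophy,
                 between_subject_cv = between_subject_cv,
                 clinical_coupling = clinical_coupling,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# strictly monotone soft clamp of a percent score into (0, 100): identity on
# [5, 95], exponential saturation outside. Monotonicity (no ties) is needed
# for the clinical_coupling = 1 perfect-rank-correlation property.
soft_clamp_pct <- function(x) {
  hi <- x > 95
  lo <- x < 5
  x[hi] <- 95 + 5 * (1 - exp(-(x[hi] - 95) / 5))
  x[lo] <- 5 - 5 * (1 - exp(-(5 - x[lo]) / 5))
  x
}

mean1_lognormal <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -s^2 / 2, s))
}

# Deterministic per-cohort manifest: per-subject phantom specs, atrophy peaks
# and clinical records. All randomness is consumed here in a fixed order.
cohort_manifest <- function(cspec, pspec) {
  stopifnot(inherits(cspec, "cohort_spec"), inherits(pspec, "phantom_spec"))
  np <- cspec$n_patients; nc <- cspec$n_controls; n <- np + nc
  cd <- CLINICAL_DEFAULTS
  set.seed(cspec$seed)
  fa <- mean1_lognormal(n, cspec$between_subject_cv)   # A-P axis factor
  fb <- mean1_lognormal(n, cspec$between_subject_cv)   # R-L axis factor
  peak <- rep(0, n)
  if (!is.null(cspec$atrophy) && !is.null(cspec$atrophy$span)) {
    jit <- mean1_lognormal(np, cspec$between_subject_cv)
    peak[seq_len(np)] <- cspec$atrophy$peak * jit
  }
  group <- rep(c("patient", "control"), c(np, nc))
  id <- c(sprintf("P%02d", seq_len(np)), sprintf("C%02d", seq_len(nc)))

  # clinical scores: latent = coupling * standardized(peak) + residual noise
  eps <- matrix(rnorm(np * 4L), np, 4L)
  zp <- if (np > 1L && sd(peak[seq_len(np)]) > 0)
    as.numeric(scale(peak[seq_len(np)])) else rep(0, np)
  cc <- cspec$clinical_coupling
  latent <- cc * zp + sqrt(1 - cc^2) * eps
  pct <- sweep(sweep(latent, 2L, cd$mmt_pct_sd, "*"), 2L, cd$mmt_pct_mean, "+")
  pct <- soft_clamp_pct(pct)
  raw <- round(sweep(pct / 100, 2L, cd$mmt_max, "*"))
  arm <- rowSums(raw)
  leg <- pmin(cd$mmt_leg[["max"]],
              pmax(0, round(rnorm(np, cd$mmt_leg[["mean"]], cd$mmt_leg[["sd"]]))))
  mfm <- sapply(c("d1", "d2", "d3"), function(k)
    pmin(39, pmax(0, round(rnorm(np, cd$mfm_mean[[k]], cd$mfm_sd[[k]])))))
  als_arm <- pmin(8, pmax(0, round(rnorm(np, cd$alsfrs_arm[["mean"]], cd$alsfrs_arm[["sd"]]))))
  als_leg <- pmin(8, pmax(0, round(rnorm(np, cd$alsfrs_leg[["mean"]], cd$alsfrs_leg[["sd"]]))))
  als_oth <- pmin(32, pmax(0, round(rnorm(np, cd$alsfrs_other[["mean"]], cd$alsfrs_other[["sd"]]))))
  duration <- pmax(1, round(rnorm(np, cd$duration[["mean"]], cd$duration[["sd"]])))
  age <- pmax(18, round(c(rnorm(np, cd$age[["patient"]], cd$age[["sd"]]),
                          rnorm(nc, cd$age[["control"]], cd$age[["sd"]]))))
  sex <- c(sample(rep(c("M", "F"), c(round(np * cd$male_frac[["patient"]]),
                                     np - round(np * cd$male_frac[["patient"]])))),
           sample(rep(c("M", "F"), c(round(nc * cd$male_frac[["control"]]),
                                     nc - round(nc * cd$male_frac[["control"]])))))

  napad <- function(x) c(x, rep(NA_real_, nc))
  records <- data.frame(
    id = id, group = group, age = age, sex = sex,
    disease_duration_years = napad(duration),
    mmt_c5 = c(raw[, 1L], rep(cd$mmt_max[["c5"]], nc)),
    mmt_c6 = c(raw[, 2L], rep(cd$mmt_max[["c6"]], nc)),
    mmt_c7 = c(raw[, 3L], rep(cd$mmt_max[["c7"]], nc)),
    mmt_c8 = c(raw[, 4L], rep(cd$mmt_max[["c8"]], nc)),
    mmt_pct_c5 = c(pct[, 1L], rep(100, nc)),
    mmt_pct_c6 = c(pct[, 2L], rep(100, nc)),
    mmt_pct_c7 = c(pct[, 3L], rep(100, nc)),
    mmt_pct_c8 = c(pct[, 4L], rep(100, nc)),
    mmt_arm = c(arm, rep(70, nc)),
    mmt_leg = c(leg, rep(70, nc)),
    mmt_total = c(arm + leg, rep(140, nc)),
    mfm_d1 = napad(mfm[, "d1"]), mfm_d2 = napad(mfm[, "d2"]),
    mfm_d3 = napad(mfm[, "d3"]),
    alsfrs_arm = napad(als_arm), alsfrs_leg = napad(als_leg),
    alsfrs_total = napad(als_arm + als_leg + als_oth),
    peak_atrophy = peak,
    stringsAsFactors = FALSE)

  subject_specs <- lapply(seq_len(n), function(i) {
    sp <- pspec
    sp$ap_semiaxis_mm$mm <- sp$ap_semiaxis_mm$mm * fa[i]
    sp$rl_semiaxis_mm$mm <- sp$rl_semiaxis_mm$mm * fb[i]
    sp$seed <- (pspec$seed * 10007L + i) %% 2147483647L
    sp
  })
  list(records = records, subject_specs = subject_specs, peak = peak,
       atrophy = cspec$atrophy)
}

subject_phantom <- function(manifest, i, render_volume = TRUE) {
  atr <- manifest$atrophy
  if (!is.null(atr)) atr$peak <- manifest$peak[i]
  if (manifest$peak[i] == 0) atr <- NULL
  make_phantom(manifest$subject_specs[[i]], atr, render_volume = render_volume)
}

#' Generate a synthetic cohort
#'
#' Patients carry the atrophy field (subject-level peak jittered by
#' `between_subject_cv`); controls do not. Clinical records follow the
#' `SubjectRecord` schema with MMT percent scores drawn with the configured
#' coupling to each subject's realized peak atrophy.
#'
#' @param cspec a [cohort_spec].
#' @param pspec a [phantom_spec] shared by all subjects (per-subject
#'   semi-axes are jittered).
#' @param render_volumes render noisy intensity volumes (`FALSE` keeps only
#'   masks + ground truth, which is all that mask-based analyses need).
#' @return A `cord_cohort`: list with `records` (data frame, one row per
#'   subject) and `subjects` (list of [make_phantom()] results, in record
#'   order).
#' @export
make_cohort <- function(cspec, pspec = phantom_spec(), render_volumes = TRUE) {
  man <- cohort_manifest(cspec, pspec)
  subjects <- lapply(seq_len(nrow(man$records)), function(i)
    subject_phantom(man, i, render_volume = render_volumes))
  names(subjects) <- man$records$id
  structure(list(records = man$records, subjects = subjects,
                 cohort_spec = cspec, phantom_spec = pspec),
            class = "cord_cohort")
}

#' @export
print.cord_cohort <- function(x, ...) {
  cat(sprintf("<cord_cohort> %d patients + %d controls\n",
              sum(x$records$group == "patient"),
              sum(x$records$group == "control")))
  invisible(x)
}

#' Measured morphometry profiles for a whole synthetic cohort
#'
#' Streams subject by subject (generate mask, straighten, standardize,
#' measure, discard), so memory stays flat even for working-resolution
#' cohorts. Identical seeds give profiles identical to measuring a
#' [make_cohort()] result.
#'
#' @param cspec,pspec cohort and phantom specifications.
#' @param L standard slice count; defaults to the cohort median length.
#' @param rd also compute radial-distance profiles (slower).
#' @return List with `csa` (subjects x L matrix), `rd` (subjects x (L*72)
#'   matrix with attribute `rd_dim = c(L, 72)`, or `NULL`), `records`, `L`,
#'   and `level_map`.
#' @export
cohort_profiles <- function(cspec, pspec = phantom_spec(), L = NULL, rd = FALSE) {
  man <- cohort_manifest(cspec, pspec)
  n <- nrow(man$records)
  lens <- vapply(man$subject_specs, function(s) s$n_slices_acq, integer(1L))
  if (is.null(L)) L <- lower_median(lens)
  csa <- matrix(NA_real_, n, L)
  rdm <- if (rd) matrix(NA_real_, n, L * 72L) else NULL
  for (i in seq_len(n)) {
    ph <- subject_phantom(man, i, render_volume = FALSE)
    st <- straighten(ph$mask)
    sm <- standardize_length(st$mask, L)
    csa[i, ] <- cross_sectional_areas(sm)
    if (rd) rdm[i, ] <- as.vector(radial_distances(sm))
    rm(ph, st, sm)
  }
  rownames(csa) <- man$records$id
  if (rd) {
    rownames(rdm) <- man$records$id
    attr(rdm, "rd_dim") <- c(L, 72L)
  }
  list(csa = csa, rd = rdm, records = man$records, L = L,
       level_map = label_levels(L))
}
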