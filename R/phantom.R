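# Synthetic cervical-cord phantom: a curved elliptical tube (cord) inside a
# brighter CSF sheath on a dark background, with analytic ground truth.

#' Phantom specification
#'
#' Describes one synthetic cervical cord. The default semi-axis profiles give
#' a cervical-enlargement CSA shape: ~69 mm^2 at the C2 end, peaking at
#' ~83 mm^2 near C4-C5, declining to ~60 mm^2 at C7/T1. Semi-axis control
#' points are piecewise-linear in the fractional position along the cord
#' (0 = inferior end, 1 = superior end).
#'
#' @param cord_length_mm physical length of the simulated cervical cord.
#' @param voxel_mm isotropic voxel size (0.9 mm emulates the acquisition,
#'   0.3 mm the working resolution).
#' @param fov_mm in-plane field of view (square).
#' @param centerline_amplitude_mm peak anterior-posterior bow of the
#'   centerline (residual lordosis); half-sine along the cord.
#' @param ap_semiaxis_mm,rl_semiaxis_mm data frames with columns `frac`
#'   (0..1 from inferior) and `mm`: piecewise-linear control points of the
#'   anterior-posterior and right-left ellipse semi-axes.
#' @param csf_ring_mm thickness of the CSF sheath around the cord.
#' @param intensities named vector with mean signal levels `cord`, `csf`,
#'   `background`; T2-like contrast requires csf > cord.
#' @param noise_sigma additive Gaussian noise SD (intensity units).
#' @param bias_amplitude amplitude of a multiplicative linear bias field
#'   (0.2 = +-20% across the volume).
#' @param seed RNG seed used when rendering the noisy volume.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(cord_length_mm = 124,
                         voxel_mm = 0.9,
                         fov_mm = 32,
                         centerline_amplitude_mm = 4,
                         ap_semiaxis_mm = data.frame(
                           frac = c(0, 0.35, 0.55, 1),
                           mm = c(3.8, 4.2, 4.2, 4.0)),
                         rl_semiaxis_mm = data.frame(
                           frac = c(0, 0.35, 0.55, 1),
                           mm = c(5.0, 6.3, 6.3, 5.5)),
                         csf_ring_mm = 1.5,
                         intensities = c(cord = 100, csf = 200, background = 20),
                         noise_sigma = 0,
                         bias_amplitude = 0,
                         seed = 1L) {
  stopifnot(cord_length_mm > 0, voxel_mm > 0, fov_mm > 0, csf_ring_mm >= 0)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  for (df in list(ap_semiaxis_mm, rl_semiaxis_mm)) {
    if (!all(c("frac", "mm") %in% names(df)) || any(df$mm <= 0))
      stop("semi-axis control points need columns frac/mm with mm > 0")
  }
  ints <- intensities[c("cord", "csf", "background")]
  if (anyNA(ints)) stop("intensities must name cord, csf and background")
  if (ints[["csf"]] <= ints[["cord"]])
    stop("T2-like contrast requires csf intensity > cord intensity")
  structure(list(cord_length_mm = cord_length_mm,
                 n_slices_acq = max(2L, as.integer(round(cord_length_mm / voxel_mm))),
                 voxel_mm = voxel_mm, fov_mm = fov_mm,
                 centerline_amplitude_mm = centerline_amplitude_mm,
                 ap_semiaxis_mm = ap_semiaxis_mm,
                 rl_semiaxis_mm = rl_semiaxis_mm,
                 csf_ring_mm = csf_ring_mm, intensities = ints,
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Atrophy field
#'
#' A per-slice fractional reduction applied to the phantom geometry over a
#' vertebral-level extent. Directions: `"anterior-posterior"` shrinks the A-P
#' semi-axis, `"right-left"` the R-L semi-axis, `"isotropic"` reduces area
#' (both axes by `sqrt(1 - p)`), and `"anterior"` shrinks only the anterior
#' half of the ellipse, displacing the section's center of mass posteriorly
#' (the mechanism behind apparent dorsal radial-distance loss when atrophy is
#' ventral).
#'
#' @param direction one of `"anterior-posterior"`, `"right-left"`,
#'   `"isotropic"`, `"anterior"`.
#' @param peak peak fractional reduction in `[0, 1)`; for
#'   `"anterior-posterior"` a peak of 0.20 reduces CSA by 20%.
#' @param extent character vector `c(from, to)` of vertebral levels
#'   (`"C2"`..`"C7"`) the field covers, or `NULL` for an empty field.
#' @param ramp_frac fraction of the extent used for the smoothstep ramp at
#'   each end (plateau covers the rest).
#' @param boundaries level boundary fractions as in [label_levels()].
#' @return An `atrophy_field` object; `profile_at(field, frac)` evaluates it.
#' @export
atrophy_field <- function(direction = c("anterior-posterior", "right-left",
                                        "isotropic", "anterior"),
                          peak = 0.20,
                          extent = c("C3", "C6"),
                          ramp_frac = 0.1,
                          boundaries = (1:5) / 6) {
  direction <- match.arg(direction)
  if (peak < 0 || peak >= 1) stop("peak must be in [0, 1)")
  if (!is.null(extent)) {
    span <- level_span_fractions(extent, boundaries)
  } else {
    span <- NULL
  }
  structure(list(direction = direction, peak = peak, extent = extent,
                 span = span, ramp_frac = ramp_frac),
            class = "atrophy_field")
}

# fractional span (from inferior) covered by vertebral levels from..to
level_span_fractions <- function(extent, boundaries = (1:5) / 6) {
  lv <- paste0("C", 2:7)
  i <- match(extent, lv)
  if (anyNA(i)) stop("extent levels must be C2..C7")
  i <- sort(i)
  # level C(k) occupies from-top fraction ((k-2)/..): cuts from boundaries
  cuts <- c(0, boundaries, 1)           # from-top fractions of level edges
  top <- cuts[i[1L]]
  bot <- cuts[i[length(i)] + 1L]
  c(lo = 1 - bot, hi = 1 - top)         # convert to from-inferior fractions
}

#' Evaluate an atrophy field at fractional cord positions
#'
#' @param field an [atrophy_field] (or `NULL`, giving zeros).
#' @param frac fractional positions along the cord (0 = inferior).
#' @param peak optional override of the field's peak (used for per-subject
#'   jitter).
#' @return Numeric vector of fractional reductions in `[0, 1)`.
#' @export
profile_at <- function(field, frac, peak = NULL) {
  if (is.null(field) || is.null(field$span)) return(rep(0, length(frac)))
  pk <- if (is.null(peak)) field$peak else peak
  lo <- field$span[["lo"]]; hi <- field$span[["hi"]]
  w <- hi - lo
  d <- pmin(frac - lo, hi - frac) / w    # distance to nearest edge, extent units
  s <- pmin(pmax(d / field$ramp_frac, 0), 1)
  out <- pk * (3 * s^2 - 2 * s^3)        # smoothstep ramp, plateau inside
  out[frac < lo | frac > hi] <- 0
  out
}

interp_profile <- function(df, frac) {
  approx(df$frac, df$mm, xout = frac, rule = 2)$y
}

# per-slice geometry implied by a spec + atrophy field (+ optional modifiers)
phantom_geometry <- function(spec, atrophy = NULL, peak = NULL) {
  nz <- spec$n_slices_acq
  frac <- (seq_len(nz) - 1) / (nz - 1)
  a <- interp_profile(spec$ap_semiaxis_mm, frac)
  b <- interp_profile(spec$rl_semiaxis_mm, frac)
  p <- profile_at(atrophy, frac, peak)
  a_ant <- a; a_post <- a
  dir <- if (is.null(atrophy)) "none" else atrophy$direction
  if (dir == "anterior-posterior") { a_ant <- a * (1 - p); a_post <- a_ant }
  else if (dir == "right-left")    b <- b * (1 - p)
  else if (dir == "isotropic")     { s <- sqrt(1 - p); a_ant <- a * s; a_post <- a * s; b <- b * s }
  else if (dir == "anterior")      a_ant <- a * (1 - p)
  cy <- spec$centerline_amplitude_mm * sin(pi * frac)
  csa <- pi / 2 * (a_ant + a_post) * b
  data.frame(slice = seq_len(nz) - 1L, frac = frac,
             center_x_mm = 0, center_y_mm = cy,
             a_ant_mm = a_ant, a_post_mm = a_post, b_rl_mm = b,
             atrophy = p, csa_mm2 = csa)
}

#' Generate a single cord phantom
#'
#' Renders a curved elliptical cord surrounded by a brighter CSF ring on a
#' dark background, with optional multiplicative bias field and additive
#' Gaussian noise; the mask is the noise-free ground-truth cord (a voxel is
#' cord iff its center lies inside the ellipse). Ground-truth CSA is
#' analytic: `pi * a * b` (or the half-ellipse composite for `"anterior"`
#' fields).
#'
#' @param spec a [phantom_spec].
#' @param atrophy an [atrophy_field], or `NULL` for a healthy cord.
#' @param render_volume set to `FALSE` to skip intensity rendering (returns
#'   mask and ground truth only; much faster for mask-based analyses).
#' @return List with elements `volume` ([cord_volume] or `NULL`), `mask`
#'   ([cord_mask]), and `ground_truth` (data frame of per-slice true
#'   semi-axes, centerline and CSA).
#' @export
make_phantom <- function(spec, atrophy = NULL, render_volume = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec, atrophy)
  n_in <- as.integer(round(spec$fov_mm / spec$voxel_mm))
  half <- spec$fov_mm / 2
  reach <- max(geo$b_rl_mm, geo$a_ant_mm + abs(geo$center_y_mm),
               geo$a_post_mm + abs(geo$center_y_mm)) + spec$csf_ring_mm
  if (reach > half - spec$voxel_mm)
    stop(sprintf("phantom cross-section (%.1f mm reach) exceeds the %.1f mm field of view",
                 reach, spec$fov_mm))
  # voxel-center coordinates, mm, origin at FOV center
  coord <- (seq_len(n_in) - (n_in + 1) / 2) * spec$voxel_mm
  X <- matrix(coord, n_in, n_in)               # right-left
  Y <- matrix(coord, n_in, n_in, byrow = TRUE) # anterior-posterior (+ = anterior)
  nz <- spec$n_slices_acq
  mask <- array(FALSE, c(n_in, n_in, nz))
  vol <- if (render_volume) array(spec$intensities[["background"]],
                                  c(n_in, n_in, nz)) else NULL
  ring <- spec$csf_ring_mm
  for (z in seq_len(nz)) {
    dy <- Y - geo$center_y_mm[z]
    ay <- ifelse(dy >= 0, geo$a_ant_mm[z], geo$a_post_mm[z])
    inside <- (X / geo$b_rl_mm[z])^2 + (dy / ay)^2 <= 1
    mask[, , z] <- inside
    if (render_volume) {
      sheath <- (X / (geo$b_rl_mm[z] + ring))^2 + (dy / (ay + ring))^2 <= 1
      sl <- vol[, , z]
      sl[sheath] <- spec$intensities[["csf"]]
      sl[inside] <- spec$intensities[["cord"]]
      vol[, , z] <- sl
    }
  }
  volume <- NULL
  if (render_volume) {
    set.seed(spec$seed)
    if (spec$bias_amplitude != 0) {
      xn <- (seq_len(n_in) - 1) / (n_in - 1) - 0.5
      zn <- (seq_len(nz) - 1) / (nz - 1) - 0.5
      bias <- 1 + spec$bias_amplitude *
        (outer(array(xn, c(n_in)), rep(1, n_in)) %o% rep(1, nz) +
           rep(1, n_in) %o% rep(1, n_in) %o% zn) / 2
      vol <- vol * bias
    }
    if (spec$noise_sigma > 0)
      vol <- vol + rnorm(length(vol), sd = spec$noise_sigma)
    volume <- cord_volume(vol, spec$voxel_mm)
  }
  list(volume = volume,
       mask = cord_mask(mask, spec$voxel_mm),
       ground_truth = geo)
}
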