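# Cord standardization: per-slice straightening (integer-voxel translations,
# exactly area-preserving) and nearest-neighbor length normalization to a
# common slice count so cohorts can be compared slice-by-slice.

#' Straighten a cord mask
#'
#' Each axial slice is translated by an integer number of voxels so that its
#' center of mass lands on the common in-plane grid center. Translation-only
#' straightening preserves per-slice areas (and radial distances) exactly.
#'
#' @param mask a [cord_mask]; every slice must be nonempty.
#' @return List with `mask` (straightened [cord_mask]), `centerline` (data
#'   frame `z`, `x_mm`, `y_mm`: original per-slice centers of mass, mm,
#'   0-based grid origin) and `shifts` (integer matrix of applied per-slice
#'   voxel shifts).
#' @export
straighten <- function(mask) {
  stopifnot(inherits(mask, "cord_mask"))
  d <- dim(mask$grid)
  ctr <- (d[1:2] + 1) / 2
  nz <- d[3L]
  out <- array(FALSE, d)
  cl <- matrix(NA_real_, nz, 2L)
  shifts <- matrix(0L, nz, 2L)
  for (z in seq_len(nz)) {
    sl <- mask$grid[, , z]
    com <- slice_com(sl)
    if (anyNA(com))
      stop(sprintf("slice %d is empty; straightening requires nonempty slices", z - 1L))
    cl[z, ] <- com
    sh <- as.integer(round(ctr - com))
    shifts[z, ] <- sh
    si <- which(sl)
    nr <- d[1L]
    i <- ((si - 1L) %% nr) + 1L + sh[1L]
    j <- ((si - 1L) %/% nr) + 1L + sh[2L]
    if (any(i < 1L | i > d[1L] | j < 1L | j > d[2L]))
      stop(sprintf("slice %d: mask would leave the field of view when centered", z - 1L))
    nsl <- array(FALSE, d[1:2])
    nsl[cbind(i, j)] <- TRUE
    out[, , z] <- nsl
  }
  centerline <- data.frame(z = seq_len(nz) - 1L,
                           x_mm = (cl[, 1L] - 1) * mask$voxel_mm[1L],
                           y_mm = (cl[, 2L] - 1) * mask$voxel_mm[2L])
  list(mask = cord_mask(out, mask$voxel_mm), centerline = centerline,
       shifts = shifts)
}

#' Standardize a straightened mask to a common length
#'
#' Resamples along the inferior-superior axis to exactly `L` slices with
#' nearest-neighbor interpolation (binary values preserved exactly). Output
#' slice `k` (0-based) maps to input slice `round(k * (N-1) / (L-1))`;
#' half-integer ties round toward inferior, making outputs bit-reproducible.
#' The operation is idempotent at length `L`.
#'
#' @param mask straightened [cord_mask] with `N >= 2` slices.
#' @param L standard slice count (>= 2); the cohort default is the median
#'   cord length (413 slices at 0.3 mm for a full cervical cord).
#' @return A `standardized_mask` (a [cord_mask] subclass with exactly `L`
#'   slices).
#' @export
standardize_length <- function(mask, L = 413L) {
  stopifnot(inherits(mask, "cord_mask"))
  L <- as.integer(L)
  if (L < 2L) stop("L must be >= 2")
  N <- n_slices(mask)
  if (N < 2L) stop("mask must have at least 2 slices")
  x <- (seq_len(L) - 1) * (N - 1) / (L - 1)
  src <- as.integer(ceiling(x - 0.5)) + 1L   # round half toward inferior
  src <- pmin(pmax(src, 1L), N)
  out <- mask$grid[, , src, drop = FALSE]
  res <- cord_mask(out, mask$voxel_mm)
  class(res) <- c("standardized_mask", class(res))
  res$L <- L
  res
}

lower_median <- function(x) {
  x <- sort(x)
  x[[floor((length(x) + 1) / 2)]]
}

#' Cohort standard length
#'
#' Median of per-subject slice counts; for an even number of subjects the
#' lower median is used so the target length is an actually observed one.
#'
#' @param masks list of [cord_mask] objects, or an integer vector of slice
#'   counts.
#' @return Integer standard length.
#' @export
cohort_standard_length <- function(masks) {
  if (length(masks) == 0L) stop("need at least one mask")
  lens <- if (is.numeric(masks)) as.integer(masks)
          else vapply(masks, n_slices, integer(1L))
  as.integer(lower_median(lens))
}
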