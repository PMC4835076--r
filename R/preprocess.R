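# Preprocessing: polynomial bias-field correction and crop + cubic
# resampling of the cervical region to the working resolution.

#' Landmark pair delimiting the cervical cord
#'
#' Superior landmark: upper limit of the odontoid process of C2; inferior:
#' middle of the C7/T1 vertebral body. Coordinates are 0-based voxel indices
#' `(i, j, k)`; slice 0 is the most inferior slice, so the superior landmark
#' must have the larger `k`.
#'
#' @param superior,inferior integer vectors of length 3.
#' @return A `landmark_pair` object.
#' @export
landmark_pair <- function(superior, inferior) {
  superior <- as.integer(superior); inferior <- as.integer(inferior)
  if (length(superior) != 3L || length(inferior) != 3L)
    stop("landmarks must be length-3 voxel coordinates")
  if (superior[3L] <= inferior[3L])
    stop("superior landmark must lie strictly above the inferior landmark")
  structure(list(superior = superior, inferior = inferior),
            class = "landmark_pair")
}

#' Read landmarks from a sidecar JSON file
#'
#' Expected layout: `{"superior": [i,j,k], "inferior": [i,j,k]}` with 0-based
#' voxel indices.
#'
#' @param path JSON file path.
#' @return A [landmark_pair].
#' @export
read_landmarks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_pair(x$superior, x$inferior)
}

#' Polynomial bias-field correction
#'
#' A stand-in for external non-uniformity correction: fits a low-order
#' polynomial in normalized (x, y, z) to the log-intensity of bright voxels
#' (above the volume median), divides the volume by the exponentiated fit,
#' and rescales so the mean intensity is preserved. `poly_order = 0` is a
#' pure global rescale (identity once the mean is restored).
#'
#' @param vol a [cord_volume].
#' @param poly_order total polynomial degree, >= 0.
#' @param max_fit_voxels cap on bright voxels used for the fit (subsampled
#'   with a deterministic stride).
#' @return Bias-corrected [cord_volume].
#' @export
correct_bias <- function(vol, poly_order = 2L, max_fit_voxels = 20000L) {
  stopifnot(inherits(vol, "cord_volume"))
  if (poly_order < 0) stop("poly_order must be >= 0")
  g <- vol$grid
  if (all(g == 0)) stop("cannot bias-correct an all-zero volume")
  mu0 <- mean(g)
  if (poly_order == 0L) return(vol)   # global rescale that preserves the mean
  d <- dim(g)
  # fit on the brightest tissue class only (CSF-like): within one class the
  # log-intensity variation is the bias field, not anatomy
  ref <- quantile(g, 0.995, names = FALSE)
  bright <- which(g > 0.7 * ref & g > 0)
  if (length(bright) < 50L) stop("too few bright voxels for a bias fit")
  if (length(bright) > max_fit_voxels) {
    stride <- ceiling(length(bright) / max_fit_voxels)
    bright <- bright[seq(1L, length(bright), by = stride)]
  }
  ijk <- arrayInd(bright, d)
  nrm <- function(i, n) if (n > 1L) (i - 1) / (n - 1) - 0.5 else rep(0, length(i))
  xb <- nrm(ijk[, 1L], d[1L]); yb <- nrm(ijk[, 2L], d[2L]); zb <- nrm(ijk[, 3L], d[3L])
  basis <- function(x, y, z) {
    cols <- list(rep(1, length(x)))
    for (deg in seq_len(poly_order))
      for (px in 0:deg) for (py in 0:(deg - px)) {
        pz <- deg - px - py
        cols[[length(cols) + 1L]] <- x^px * y^py * z^pz
      }
    do.call(cbind, cols)
  }
  B <- basis(xb, yb, zb)
  beta <- qr.coef(qr(B), log(g[bright]))
  beta[is.na(beta)] <- 0
  # evaluate the fitted log-bias on the full grid, slice by slice
  xg <- nrm(seq_len(d[1L]), d[1L]); yg <- nrm(seq_len(d[2L]), d[2L])
  zg <- nrm(seq_len(d[3L]), d[3L])
  Xf <- rep(xg, times = d[2L]); Yf <- rep(yg, each = d[1L])
  out <- g
  for (z in seq_len(d[3L])) {
    lb <- as.numeric(basis(Xf, Yf, rep(zg[z], length(Xf))) %*% beta)
    out[, , z] <- g[, , z] / exp(matrix(lb - beta[1L], d[1L], d[2L]))
  }
  out <- out * (mu0 / mean(out))
  cord_volume(out, vol$voxel_mm)
}

# --- separable cubic-convolution (Catmull-Rom) resampling -----------------

# weight matrix mapping n_in samples to n_out samples; output index k
# (0-based) sits at input coordinate k * scale. Constants are reproduced
# exactly (weights sum to 1); border samples are clamped.
cubic_weights <- function(n_in, n_out, scale) {
  t <- (seq_len(n_out) - 1) * scale
  i0 <- floor(t)
  f <- t - i0
  w <- cbind(0.5 * (-f + 2 * f^2 - f^3),
             0.5 * (2 - 5 * f^2 + 3 * f^3),
             0.5 * (f + 4 * f^2 - 3 * f^3),
             0.5 * (-f^2 + f^3))
  A <- matrix(0, n_out, n_in)
  for (m in 1:4) {
    idx <- pmin(pmax(i0 + (m - 2L), 0), n_in - 1L) + 1L
    A[cbind(seq_len(n_out), idx)] <- A[cbind(seq_len(n_out), idx)] + w[, m]
  }
  A
}

resample_axis <- function(arr, axis, A) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  out <- A %*% m
  d2 <- d[perm]; d2[1L] <- nrow(A)
  aperm(array(out, d2), order(perm))
}

#' Crop to the cervical region and resample to the working resolution
#'
#' Crops the volume to the landmark interval along the inferior-superior axis
#' (inclusive), optionally restricts the in-plane field of view to a margin
#' around the image center, then resamples all three axes to
#' `target_voxel_mm` with separable cubic (Catmull-Rom) interpolation.
#' The output slice count is `round(n_in * voxel_in / target)`, so a 150
#' slice interval at 0.9 mm becomes 450 slices at 0.3 mm.
#'
#' @param vol a [cord_volume].
#' @param lm a [landmark_pair] (coordinates in `vol`'s voxel grid).
#' @param target_voxel_mm working voxel size (isotropic), default 0.3.
#' @param margin_mm in-plane half-width kept around the image center;
#'   `Inf` keeps the full field of view.
#' @return Cropped and resampled [cord_volume].
#' @export
crop_and_resample <- function(vol, lm, target_voxel_mm = 0.3, margin_mm = 20) {
  stopifnot(inherits(vol, "cord_volume"), inherits(lm, "landmark_pair"))
  d <- dim(vol$grid)
  k0 <- lm$inferior[3L] + 1L; k1 <- lm$superior[3L] + 1L
  if (k0 < 1L || k1 > d[3L]) stop("landmarks outside the volume")
  g <- vol$grid[, , k0:k1, drop = FALSE]
  vx <- vol$voxel_mm
  keep_inplane <- function(n, voxel) {
    if (!is.finite(margin_mm)) return(seq_len(n))
    ctr <- (n + 1) / 2
    half <- margin_mm / voxel
    max(1L, ceiling(ctr - half)):min(n, floor(ctr + half))
  }
  ii <- keep_inplane(d[1L], vx[1L]); jj <- keep_inplane(d[2L], vx[2L])
  g <- g[ii, jj, , drop = FALSE]
  dn <- dim(g)
  out <- g
  for (axis in 1:3) {
    n_in <- dn[axis]
    n_out <- max(2L, as.integer(round(n_in * vx[axis] / target_voxel_mm)))
    if (n_out == n_in && abs(vx[axis] - target_voxel_mm) < 1e-9) next
    A <- cubic_weights(n_in, n_out, scale = target_voxel_mm / vx[axis])
    out <- resample_axis(out, axis, A)
    dn <- dim(out)
  }
  # clamp cubic overshoot at hard edges to the input intensity range
  rng_in <- range(g)
  out[out < rng_in[1L]] <- rng_in[1L]
  out[out > rng_in[2L]] <- rng_in[2L]
  cord_volume(out, target_voxel_mm)
}
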