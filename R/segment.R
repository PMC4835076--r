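# Double-threshold cord segmentation (reconstruction). On T2-like contrast
# the cord sits between the dark background and the bright CSF sheath, so
# the two thresholds are local intensity quantiles bracketing the cord band:
# background < Q(t_low_q) <= cord < Q(t_high_q) <= CSF. Per axial slice the
# band's connected component containing the propagated centerline estimate
# is kept and its interior holes filled; the centerline estimate propagates
# slice-to-slice from each slice's center of mass.

#' Segment the cord with a double-threshold band method
#'
#' @param vol preprocessed [cord_volume].
#' @param seed_point 0-based voxel coordinate `(i, j, k)` inside the cord;
#'   defaults to the in-plane center of the middle slice, which is correct
#'   for volumes cropped around the cord.
#' @param t_low_q,t_high_q local-window intensity quantiles defining the
#'   cord band; must satisfy `0 < t_low_q < t_high_q < 1`. Thresholds are
#'   quantile-based, so segmentation is invariant to intensity shifts and
#'   positive rescaling.
#' @param window_mm side of the square local analysis window centered on the
#'   propagated centerline estimate (encloses cord + CSF, excludes
#'   vertebrae).
#' @param smooth apply one pass of a separable 1-2-1 smoothing kernel to the
#'   slice before the band test. Off by default: the quantile band plus
#'   hole-filling is already robust to noise, while smoothing blends
#'   boundary voxels into the cord band and dilates the mask.
#' @return A [cord_mask] with a `qc` attribute (data frame: per-slice flags
#'   `empty_result` and `interpolated`).
#' @export
segment_dtbm <- function(vol, seed_point = NULL, t_low_q = 0.5, t_high_q = 0.8,
                         window_mm = 15, smooth = FALSE) {
  stopifnot(inherits(vol, "cord_volume"))
  if (!(t_low_q > 0 && t_low_q < t_high_q && t_high_q < 1))
    stop("need 0 < t_low_q < t_high_q < 1")
  d <- dim(vol$grid)
  if (is.null(seed_point)) {
    seed_point <- c(round((d[1L] - 1) / 2), round((d[2L] - 1) / 2),
                    round((d[3L] - 1) / 2))
  }
  sp <- as.integer(seed_point) + 1L
  if (any(sp < 1L) || any(sp > d)) stop("seed_point outside the volume")
  rng <- range(vol$grid)
  if (diff(rng) <= 0) stop("volume has no intensity contrast; cannot segment")
  half <- as.integer(ceiling(window_mm / 2 / vol$voxel_mm[1L]))
  mask <- array(FALSE, d)
  qc <- data.frame(slice = seq_len(d[3L]) - 1L, empty_result = FALSE,
                   interpolated = FALSE)

  seg_slice <- function(z, center) {
    sl <- vol$grid[, , z]
    ci <- as.integer(round(center))
    ii <- max(1L, ci[1L] - half):min(d[1L], ci[1L] + half)
    jj <- max(1L, ci[2L] - half):min(d[2L], ci[2L] + half)
    win <- sl[ii, jj]
    thr <- quantile(win, c(t_low_q, t_high_q), names = FALSE)
    test <- if (smooth) smooth121(sl) else sl
    cand <- test >= thr[1L] & test < thr[2L]
    # seed at the candidate voxel (inside the window) closest to the center
    cwin <- cand[ii, jj]
    if (!any(cwin)) return(NULL)
    idx <- which(cwin)
    wi <- ii[((idx - 1L) %% length(ii)) + 1L]
    wj <- jj[((idx - 1L) %/% length(ii)) + 1L]
    k <- which.min((wi - center[1L])^2 + (wj - center[2L])^2)
    # restrict candidates to the window so distant tissue cannot attach
    cand_w <- array(FALSE, d[1:2]); cand_w[ii, jj] <- cand[ii, jj]
    comp <- component_from_seed(cand_w, c(wi[k], wj[k]))
    if (!any(comp)) return(NULL)
    comp | find_holes(comp)
  }

  z0 <- sp[3L]
  order_up <- z0:d[3L]; order_dn <- if (z0 > 1L) (z0 - 1L):1L else integer(0)
  for (dir in list(order_up, order_dn)) {
    center <- c(sp[1L], sp[2L])
    for (z in dir) {
      res <- seg_slice(z, center)
      if (is.null(res)) {
        qc$empty_result[z] <- TRUE
      } else {
        mask[, , z] <- res
        center <- slice_com(res)
      }
    }
  }
  n_empty <- sum(qc$empty_result)
  if (n_empty == d[3L])
    stop("segmentation failed on every slice (no cord-like structure found)")
  if (n_empty > 0.10 * d[3L])
    stop(sprintf("segmentation lost propagation on %d/%d slices", n_empty, d[3L]))
  if (n_empty > 0L) {   # interpolate failed slices from the nearest good one
    good <- which(!qc$empty_result)
    for (z in which(qc$empty_result)) {
      zn <- good[which.min(abs(good - z))]
      mask[, , z] <- mask[, , zn]
      qc$interpolated[z] <- TRUE
    }
  }
  out <- cord_mask(mask, vol$voxel_mm)
  attr(out, "qc") <- qc
  out
}

# separable 1-2-1 kernel, one pass, edge-replicated
smooth121 <- function(m) {
  pad_r <- rbind(m[1L, ], m, m[nrow(m), ])
  v <- (pad_r[1:nrow(m), ] + 2 * pad_r[2:(nrow(m) + 1L), ] +
          pad_r[3:(nrow(m) + 2L), ]) / 4
  pad_c <- cbind(v[, 1L], v, v[, ncol(v)])
  (pad_c[, 1:ncol(m)] + 2 * pad_c[, 2:(ncol(m) + 1L)] +
      pad_c[, 3:(ncol(m) + 2L)]) / 4
}

#' Load and validate an externally produced cord mask
#'
#' Ingests a mask edited in an external tool (NIfTI), checks it against the
#' cord-mask invariants (single component and no holes per slice), and
#' optionally repairs violations: interior holes are filled when
#' `fill = TRUE`, disconnected specks are dropped in favour of the largest
#' component; every repair is logged in the `qc` attribute.
#'
#' @param path NIfTI mask file.
#' @param reference optional [cord_volume] or [cord_mask] whose grid the mask
#'   must match.
#' @param fill fill interior holes (default `TRUE`).
#' @return A [cord_mask] with a `qc` attribute (see [validate_mask()]).
#' @export
load_external_mask <- function(path, reference = NULL, fill = TRUE) {
  v <- read_nifti(path)
  if (!is.null(reference)) {
    if (!all(dim(v$grid) == dim(reference$grid)))
      stop(sprintf("mask grid %s does not match reference grid %s",
                   paste(dim(v$grid), collapse = "x"),
                   paste(dim(reference$grid), collapse = "x")))
    if (max(abs(v$voxel_mm - reference$voxel_mm)) > 1e-4)
      stop("mask voxel size does not match reference")
  }
  m <- cord_mask(v$grid != 0, v$voxel_mm)
  out <- validate_mask(m, fill = fill, largest_component = TRUE)
  qc <- attr(out, "qc")
  if (any(qc$repaired))
    message(sprintf("external mask: repaired %d slice(s) (%d multi-component, %d with holes)",
                    sum(qc$repaired), sum(qc$n_components > 1L),
                    sum(qc$n_hole_voxels > 0L)))
  out
}
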