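# Radial-distance and cross-sectional-area morphometry on standardized
# masks. Angle convention: 0 deg = anterior (+y), counterclockwise viewed
# from superior, one radius every 5 deg (72 per slice).

#' Radial distances from the per-slice center of mass to the cord border
#'
#' For each slice a ray is cast from the center of mass along each of the
#' `360 / angular_res` angles, sampled every 0.1 voxel; the radius is the
#' distance at the first inside-to-outside transition (midpoint of the
#' bracketing samples), in mm. Slices whose center of mass falls outside the
#' mask (bent/crescent sections) are flagged in the `qc` attribute and use
#' the farthest inside sample along each ray instead.
#'
#' @param mask a `standardized_mask` (or any [cord_mask]; every slice must
#'   be nonempty).
#' @param angular_res angular resolution in degrees; must divide 360.
#' @return `L x (360/angular_res)` matrix of radii (mm), class `rd_profile`,
#'   with angle labels as column names and a `qc` attribute.
#' @export
radial_distances <- function(mask, angular_res = 5) {
  stopifnot(inherits(mask, "cord_mask"))
  if (360 %% angular_res != 0) stop("angular_res must divide 360")
  n_ang <- as.integer(360 / angular_res)
  theta <- (seq_len(n_ang) - 1) * angular_res * pi / 180
  dx <- -sin(theta); dy <- cos(theta)     # 0 deg = anterior (+y), CCW
  d <- dim(mask$grid)
  nz <- d[3L]
  vx <- mask$voxel_mm[1L]
  if (abs(mask$voxel_mm[2L] - vx) > 1e-9)
    stop("radial distances require isotropic in-plane voxels")
  out <- matrix(NA_real_, nz, n_ang)
  flagged <- logical(nz)
  step <- 0.1
  for (z in seq_len(nz)) {
    sl <- mask$grid[, , z]
    com <- slice_com(sl)
    if (anyNA(com)) stop(sprintf("slice %d is empty", z - 1L))
    idx <- which(sl)
    nr <- d[1L]
    mi <- ((idx - 1L) %% nr) + 1L
    mj <- ((idx - 1L) %/% nr) + 1L
    rmax <- sqrt(max((mi - com[1L])^2 + (mj - com[2L])^2)) + 1.5
    r <- seq(step, rmax, by = step)
    px <- round(outer(r, dx) + com[1L])   # steps x angles
    py <- round(outer(r, dy) + com[2L])
    ok <- px >= 1 & px <= d[1L] & py >= 1 & py <= d[2L]
    inside <- array(FALSE, dim(px))
    inside[ok] <- sl[cbind(px[ok], py[ok])]
    com_in <- sl[round(com[1L]), round(com[2L])]
    if (!com_in) {
      flagged[z] <- TRUE
      # farthest inside sample along each ray
      out[z, ] <- apply(inside, 2L, function(v) {
        w <- which(v)
        if (length(w) == 0L) 0.5 * step else r[max(w)]
      }) * vx
      next
    }
    ns <- length(r)
    member <- function(rr, a) {
      xi <- round(com[1L] + rr * dx[a]); yi <- round(com[2L] + rr * dy[a])
      xi >= 1 && xi <= d[1L] && yi >= 1 && yi <= d[2L] && sl[xi, yi]
    }
    for (a in seq_len(n_ang)) {
      v <- inside[, a]
      tr <- which(v[-ns] & !v[-1L])
      if (length(tr) > 0L) {
        # bisect the membership step between the bracketing samples
        lo <- r[tr[1L]]; hi <- r[tr[1L] + 1L]
        for (it in 1:12) {
          mid <- (lo + hi) / 2
          if (member(mid, a)) lo <- mid else hi <- mid
        }
        out[z, a] <- (lo + hi) / 2
      } else {
        out[z, a] <- r[max(which(v))]
      }
    }
    out[z, ] <- out[z, ] * vx
  }
  dimnames(out) <- list(NULL, sprintf("deg%03d", as.integer((seq_len(n_ang) - 1) * angular_res)))
  structure(out, class = c("rd_profile", "matrix", "array"),
            qc = data.frame(slice = seq_len(nz) - 1L, com_outside = flagged),
            voxel_mm = vx)
}

#' Cross-sectional area profile
#'
#' Area covered by the mask in each axial slice: voxel count times in-plane
#' voxel area (0.09 mm^2 on the 0.3 mm working grid).
#'
#' @param mask a [cord_mask]; every slice must be nonempty.
#' @return Length-`L` numeric vector of areas (mm^2), class `csa_profile`.
#' @export
cross_sectional_areas <- function(mask) {
  stopifnot(inherits(mask, "cord_mask"))
  counts <- slice_counts(mask)
  if (any(counts == 0L))
    stop(sprintf("slice %d is empty; CSA is undefined",
                 which(counts == 0L)[1L] - 1L))
  area <- counts * mask$voxel_mm[1L] * mask$voxel_mm[2L]
  structure(as.numeric(area), class = "csa_profile",
            voxel_mm = mask$voxel_mm[1L])
}

#' Vertebral level map for a standardized cord
#'
#' Slices are partitioned into vertebral levels C2 (superior) .. C7
#' (inferior) from fractional boundaries of the C2 -> C7/T1 span. Slice 0 is
#' the most inferior slice; intervals are half-open `[start, end)` in
#' 0-based standardized slice indices, ordered superior to inferior,
#' non-overlapping and covering `[0, L)`.
#'
#' @param L standard slice count.
#' @param boundaries strictly increasing fractions in (0,1): from-top
#'   positions of the C2/C3 .. C6/C7 boundaries (default equal sixths).
#' @return A `vertebral_level_map`: data frame with columns `level`,
#'   `start`, `end` plus attribute `L`.
#' @export
label_levels <- function(L, boundaries = (1:5) / 6) {
  L <- as.integer(L)
  if (length(boundaries) != 5L || any(diff(boundaries) <= 0) ||
      any(boundaries <= 0) || any(boundaries >= 1))
    stop("boundaries must be 5 strictly increasing fractions in (0,1)")
  cuts <- c(0, boundaries, 1)             # from-top fractions of level edges
  idx <- L - round(cuts * L)              # from-inferior slice index of each edge
  df <- data.frame(level = paste0("C", 2:7),
                   start = as.integer(idx[2:7]),
                   end = as.integer(idx[1:6]))
  structure(df, class = c("vertebral_level_map", "data.frame"), L = L)
}

#' Map vertebral levels to the spinal segments they overlie
#'
#' The cervical cord sits rostral to its vertebrae: a single vertebral level
#' `Ck` overlies spinal segments `C(k+1)` and `C(k+2)`, and a span `Ck`-`Cm`
#' overlies `C(k+1)`-`C(m+1)` (e.g. C3-C6 vertebral levels correspond to
#' C4-C7 spinal segments; the C4 vertebral level to C5-C6).
#'
#' @param from,to vertebral level names (`"C2"`..`"C7"`); `to` defaults to
#'   `from`.
#' @return Character vector of spinal segment names.
#' @export
vertebral_to_segments <- function(from, to = from) {
  k <- as.integer(sub("^C", "", from))
  m <- as.integer(sub("^C", "", to))
  if (anyNA(c(k, m)) || m < k) stop("levels must be like 'C3' with to >= from")
  paste0("C", seq(k + 1L, max(m + 1L, k + 2L)))
}

#' Slice indices covered by a span of vertebral levels
#'
#' @param map a [label_levels()] result.
#' @param from,to vertebral level names.
#' @return Integer vector of 0-based standardized slice indices.
#' @export
level_slices <- function(map, from, to = from) {
  rows <- match(c(from, to), map$level)
  if (anyNA(rows)) stop("unknown vertebral level")
  lo <- min(map$start[rows[2L]], map$start[rows[1L]])
  hi <- max(map$end[rows[1L]], map$end[rows[2L]])
  seq.int(lo, hi - 1L)
}
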