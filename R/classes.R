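#' Cord volume container
#'
#' A 3D scalar intensity grid with voxel spacing. Axes follow the package
#' convention (right-left, anterior-posterior, inferior-superior); slice 1 of
#' the third axis is the most inferior slice.
#'
#' @param grid numeric 3D array of intensities.
#' @param voxel_mm voxel size in mm; scalar (isotropic) or length-3 vector.
#' @return An object of class `cord_volume`.
#' @export
cord_volume <- function(grid, voxel_mm) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array")
  if (!all(is.finite(grid)))
    stop("cord_volume intensities must be finite")
  voxel_mm <- as_voxel3(voxel_mm)
  structure(list(grid = grid, voxel_mm = voxel_mm),
            class = c("cord_volume", "cord_image"))
}

#' Binary cord mask container
#'
#' @param grid logical (or 0/1) 3D array on the same grid as its volume.
#' @param voxel_mm voxel size in mm; scalar or length-3.
#' @return An object of class `cord_mask`.
#' @export
cord_mask <- function(grid, voxel_mm) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array")
  storage.mode(grid) <- "logical"
  if (anyNA(grid)) stop("cord_mask may not contain NA")
  voxel_mm <- as_voxel3(voxel_mm)
  structure(list(grid = grid, voxel_mm = voxel_mm),
            class = c("cord_mask", "cord_image"))
}

as_voxel3 <- function(voxel_mm) {
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("`voxel_mm` must be 1 or 3 positive finite values")
  voxel_mm
}

#' @export
print.cord_image <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<%s> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              class(x)[1L], d[1L], d[2L], d[3L],
              x$voxel_mm[1L], x$voxel_mm[2L], x$voxel_mm[3L]))
  invisible(x)
}

#' @export
dim.cord_image <- function(x) dim(x$grid)

n_slices <- function(x) dim(x$grid)[3L]

mask_slice <- function(mask, z) mask$grid[, , z]

# center of mass of a logical slice, 1-based voxel coordinates c(x, y)
slice_com <- function(sl) {
  idx <- which(sl)
  if (length(idx) == 0L) return(c(NA_real_, NA_real_))
  nr <- nrow(sl)
  i <- ((idx - 1L) %% nr) + 1L
  j <- ((idx - 1L) %/% nr) + 1L
  c(mean(i), mean(j))
}

slice_counts <- function(mask) {
  apply(mask$grid, 3L, sum)
}

#' Validate cord-mask invariants
#'
#' Checks, per axial slice, that the mask is nonempty, a single 4-connected
#' component, and free of interior holes. Violations are reported per slice.
#'
#' @param mask a [cord_mask].
#' @param fill fill interior holes instead of reporting them as violations.
#' @param largest_component keep only the largest connected component on
#'   multi-component slices (logged) instead of failing.
#' @return The (possibly repaired) mask, with a `qc` attribute: a data frame
#'   with one row per slice (columns `slice`, `n_components`, `n_hole_voxels`,
#'   `empty`, plus repair flags).
#' @export
validate_mask <- function(mask, fill = FALSE, largest_component = FALSE) {
  stopifnot(inherits(mask, "cord_mask"))
  nz <- n_slices(mask)
  qc <- data.frame(slice = seq_len(nz) - 1L, n_components = 0L,
                   n_hole_voxels = 0L, empty = FALSE,
                   repaired = FALSE)
  for (z in seq_len(nz)) {
    sl <- mask$grid[, , z]
    if (!any(sl)) { qc$empty[z] <- TRUE; next }
    lab <- label_components(sl)
    qc$n_components[z] <- lab$n
    if (lab$n > 1L) {
      if (!largest_component)
        stop(sprintf("slice %d has %d connected components", z - 1L, lab$n))
      keep <- which.max(tabulate(lab$labels[lab$labels > 0L]))
      sl <- array(lab$labels == keep, dim = dim(sl))
      qc$repaired[z] <- TRUE
    }
    holes <- find_holes(sl)
    qc$n_hole_voxels[z] <- sum(holes)
    if (any(holes)) {
      if (!fill)
        stop(sprintf("slice %d has %d interior hole voxels", z - 1L, sum(holes)))
      sl <- sl | holes
      qc$repaired[z] <- TRUE
    }
    mask$grid[, , z] <- sl
  }
  attr(mask, "qc") <- qc
  mask
}

# --- small 2D binary morphology helpers (4-connectivity) ------------------

shift2 <- function(m, di, dj) {
  n <- dim(m)
  out <- array(FALSE, n)
  si <- max(1L, 1L + di):min(n[1L], n[1L] + di)
  sj <- max(1L, 1L + dj):min(n[2L], n[2L] + dj)
  out[si, sj] <- m[si - di, sj - dj]
  out
}

dilate4 <- function(m) {
  m | shift2(m, 1L, 0L) | shift2(m, -1L, 0L) |
    shift2(m, 0L, 1L) | shift2(m, 0L, -1L)
}

# connected component containing seed (4-connectivity); seed = c(i, j)
component_from_seed <- function(cand, seed) {
  comp <- array(FALSE, dim(cand))
  if (!cand[seed[1L], seed[2L]]) return(comp)
  comp[seed[1L], seed[2L]] <- TRUE
  repeat {
    grown <- dilate4(comp) & cand
    if (sum(grown) == sum(comp)) return(comp)
    comp <- grown
  }
}

# all components; returns list(n, labels matrix of integers, 0 = background)
label_components <- function(m) {
  labels <- array(0L, dim(m))
  remaining <- m
  n <- 0L
  while (any(remaining)) {
    idx <- which(remaining)[1L]
    nr <- nrow(m)
    seed <- c(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L)
    comp <- component_from_seed(remaining, seed)
    n <- n + 1L
    labels[comp] <- n
    remaining <- remaining & !comp
  }
  list(n = n, labels = labels)
}

# interior holes: background voxels not reachable from the slice border
find_holes <- function(m) {
  bg <- !m
  reach <- array(FALSE, dim(m))
  reach[1L, ] <- bg[1L, ]; reach[nrow(m), ] <- bg[nrow(m), ]
  reach[, 1L] <- reach[, 1L] | bg[, 1L]
  reach[, ncol(m)] <- reach[, ncol(m)] | bg[, ncol(m)]
  repeat {
    grown <- dilate4(reach) & bg
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  bg & !reach
}
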