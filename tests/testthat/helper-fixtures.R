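# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures are stored.

dice_overlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# small working-resolution phantom (0.3 mm grid, no preprocessing needed)
small_phantom_spec <- function(..., cord_length_mm = 18, voxel_mm = 0.3,
                               fov_mm = 30, centerline_amplitude_mm = 2,
                               noise_sigma = 0) {
  phantom_spec(cord_length_mm = cord_length_mm, voxel_mm = voxel_mm,
               fov_mm = fov_mm,
               centerline_amplitude_mm = centerline_amplitude_mm,
               noise_sigma = noise_sigma, ...)
}

# constant-ellipse tube spec: semi-axes a (A-P) and b (R-L) everywhere
tube_spec <- function(a, b, n_slices = 5, voxel_mm = 0.3, fov_mm = 24,
                      bow = 0, ...) {
  phantom_spec(cord_length_mm = n_slices * voxel_mm, voxel_mm = voxel_mm,
               fov_mm = fov_mm, centerline_amplitude_mm = bow,
               ap_semiaxis_mm = data.frame(frac = c(0, 1), mm = c(a, a)),
               rl_semiaxis_mm = data.frame(frac = c(0, 1), mm = c(b, b)),
               ...)
}

# single-slice mask from a logical matrix
one_slice_mask <- function(m, voxel_mm = 0.3) {
  cord_mask(array(m, c(dim(m), 1L)), voxel_mm)
}

# rasterize a convex polygon (vertices in voxel units) on an n x n grid:
# voxel center inside iff on the inner side of every edge
rasterize_convex <- function(verts, n) {
  ch <- grDevices::chull(verts)
  v <- verts[ch, , drop = FALSE]
  k <- nrow(v)
  nxt <- c(2:k, 1L)
  s <- sum(v[, 1L] * v[nxt, 2L] - v[nxt, 1L] * v[, 2L])  # 2x signed area
  xs <- matrix(rep(seq_len(n), n), n, n)
  ys <- t(xs)
  inside <- array(TRUE, c(n, n))
  for (e in seq_len(k)) {
    p <- v[e, ]; q <- v[nxt[e], ]
    cr <- (q[1L] - p[1L]) * (ys - p[2L]) - (q[2L] - p[2L]) * (xs - p[1L])
    inside <- inside & if (s > 0) cr >= 0 else cr <= 0
  }
  if (sum(inside) < 10L) return(NULL)
  inside
}

# random convex polygon with bounded curvature (jittered rotated ellipse
# hull): grazing edges stay short, so the 5-degree binned boundary-pixel
# oracle is comparable to exact ray casting within one voxel diagonal
random_convex_mask <- function(n = 50, n_pts = 24, rmin = 7, rmax = 13) {
  ctr <- (n + 1) / 2
  th <- sort(runif(n_pts, 0, 2 * pi))
  a <- runif(1, rmin, rmax); b <- runif(1, rmin, rmax)
  phi <- runif(1, 0, pi)
  jit <- 1 + runif(n_pts, -0.06, 0.06)
  verts <- cbind(ctr + jit * (a * cos(th) * cos(phi) - b * sin(th) * sin(phi)),
                 ctr + jit * (a * cos(th) * sin(phi) + b * sin(th) * cos(phi)))
  rasterize_convex(verts, n)
}
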