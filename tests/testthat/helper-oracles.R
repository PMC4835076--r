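# Independent oracles kept deliberately separate from the implementation
# paths they check.

# boundary-pixel radial-distance oracle: per 5-degree bin, the maximum
# distance from the center of mass to any boundary pixel whose direction
# falls in the bin. Returns radii in mm with NA for empty bins.
rd_boundary_oracle <- function(slice, voxel_mm = 0.3, angular_res = 5) {
  idx <- which(slice)
  nr <- nrow(slice)
  i <- ((idx - 1L) %% nr) + 1L
  j <- ((idx - 1L) %/% nr) + 1L
  com <- c(mean(i), mean(j))
  # boundary = mask pixel with a 4-neighbour outside the mask (or grid edge)
  on_border <- vapply(seq_along(idx), function(k) {
    ii <- i[k]; jj <- j[k]
    ii == 1L || ii == nrow(slice) || jj == 1L || jj == ncol(slice) ||
      !slice[ii - 1L, jj] || !slice[ii + 1L, jj] ||
      !slice[ii, jj - 1L] || !slice[ii, jj + 1L]
  }, logical(1L))
  u <- i[on_border] - com[1L]
  v <- j[on_border] - com[2L]
  # angle convention: direction (dx, dy) = (-sin t, cos t), 0 deg = anterior
  ang <- (atan2(-u, v) * 180 / pi) %% 360
  bin <- (round(ang / angular_res) %% (360 / angular_res)) + 1L
  r <- sqrt(u^2 + v^2) * voxel_mm
  out <- rep(NA_real_, 360 / angular_res)
  for (k in seq_along(bin)) {
    if (is.na(out[bin[k]]) || r[k] > out[bin[k]]) out[bin[k]] <- r[k]
  }
  out
}

# exhaustive permutation oracle for small two-group comparisons:
# exact p over all choose(n, nc) relabelings, statistic mean(C) - mean(P)
perm_exact_oracle <- function(patients, controls, side = "decrease") {
  P <- as.matrix(patients); C <- as.matrix(controls)
  x <- rbind(C, P)
  nc <- nrow(C); n <- nrow(x)
  combos <- utils::combn(n, nc)
  tobs <- colMeans(C) - colMeans(P)
  p <- numeric(ncol(x))
  for (s in seq_len(ncol(x))) {
    tstar <- apply(combos, 2L, function(ix)
      mean(x[ix, s]) - mean(x[-ix, s]))
    p[s] <- switch(side,
      decrease = mean(tstar >= tobs[s] - 1e-12),
      increase = mean(tstar <= tobs[s] + 1e-12))
  }
  p
}

# 2^n sign-flip oracle for the paired signed-rank test (two-sided)
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.numeric(signs %*% r)
  p_le <- mean(Vs <= V + 1e-12)
  p_ge <- mean(Vs >= V - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}
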