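# Analytic raster fixtures shared across the test files. All are built in
# code at test time; sizes keep feature dimensions >= 6 px so discretization
# error stays inside the documented tolerances.

disc_mask <- function(R, n = 2 * R + 11) {
  x <- seq_len(n) - (n + 1) / 2
  (outer(x^2, x^2, "+") <= R^2) * 1
}

annulus_mask <- function(R, r, n = 2 * R + 11) {
  x <- seq_len(n) - (n + 1) / 2
  d2 <- outer(x^2, x^2, "+")
  (d2 <= R^2 & d2 > r^2) * 1
}

ellipse_mask <- function(a, b, n = 2 * max(a, b) + 11) {
  x <- seq_len(n) - (n + 1) / 2
  (outer(x^2 / b^2, x^2 / a^2, "+") <= 1) * 1
}

ball_volume <- function(r, n = 2 * r + 9) {
  x <- seq_len(n) - (n + 1) / 2
  v <- array(0L, c(n, n, n))
  for (k in seq_len(n))
    v[k, , ] <- (outer(x^2, x^2, "+") + x[k]^2 <= r^2) * 1L
  v
}

tube_volume <- function(R, r, n_slices, n = 2 * R + 11) {
  a <- annulus_mask(R, r, n)
  v <- array(0L, c(n_slices, n, n))
  for (k in seq_len(n_slices)) v[k, , ] <- a
  v
}

torus_volume <- function(R_major, r_minor, n = 2 * (R_major + r_minor) + 9) {
  x <- seq_len(n) - (n + 1) / 2
  v <- array(0L, c(n, n, n))
  for (k in seq_len(n))
    v[k, , ] <- (outer(x, x, function(i, j)
      (sqrt(i^2 + j^2) - R_major)^2) + x[k]^2 <= r_minor^2) * 1L
  v
}

# axis-aligned plate spanning the full cross-section, thickness t along rows
plate_volume <- function(t, nx = 30, ny = 40, nz = 40) {
  lo <- floor((nx - t) / 2) + 1
  v <- array(0L, c(nz, nx, ny))
  v[, lo:(lo + t - 1), ] <- 1L
  v
}

# cylinder rod along the slice axis, radius r
rod_volume <- function(r, n_slices = 40, n = 2 * r + 19) {
  x <- seq_len(n) - (n + 1) / 2
  xy <- (outer(x^2, x^2, "+") <= r^2) * 1L
  v <- array(0L, c(n_slices, n, n))
  for (k in seq_len(n_slices)) v[k, , ] <- xy
  v
}

# independent brute-force Euler characteristic: enumerate distinct vertices,
# edges, faces and cubes of the union of closed unit cubes by coordinate keys
euler_bruteforce <- function(vol) {
  idx <- which(vol > 0, arr.ind = TRUE)
  keys <- function(offsets) {
    out <- character(0)
    for (o in seq_len(nrow(offsets)))
      out <- c(out, paste(idx[, 1] + offsets[o, 1], idx[, 2] + offsets[o, 2],
                          idx[, 3] + offsets[o, 3], sep = ","))
    length(unique(out))
  }
  g <- function(...) as.matrix(expand.grid(...))
  nV <- keys(g(0:1, 0:1, 0:1))
  nE <- keys(g(0, 0:1, 0:1)) + keys(g(0:1, 0, 0:1)) + keys(g(0:1, 0:1, 0))
  # distinct faces: perpendicular to each axis, offset along the other two;
  # tag with the axis so faces of different orientation never collide
  nF <- 0
  for (ax in 1:3) {
    out <- character(0)
    for (o in 0:1) {
      sh <- c(0, 0, 0)
      sh[ax] <- o
      out <- c(out, paste(ax, idx[, 1] + sh[1], idx[, 2] + sh[2],
                          idx[, 3] + sh[3], sep = ","))
    }
    nF <- nF + length(unique(out))
  }
  nV - nE + nF - nrow(idx)
}

small_phantom <- function(seed = 7, n = 40, decay = 0.02, pattern = "plates",
                          ba = 0.25) {
  phantom_spec(length_slices = n, outer_radius_px = 45, inner_radius_px = 36,
               growth_plate_slice = as.integer(round(n * 0.8)),
               trabecular_pattern = pattern, lattice_thickness_px = 6,
               lattice_period_px = 18, epiphysis_ba_ta = ba,
               density_decay = decay, seed = seed, voxel_size_mm = 0.02,
               bone_length_mm = 2.0)
}
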