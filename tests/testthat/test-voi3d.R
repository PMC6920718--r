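# Percent-length VOI extraction and 3D morphometry.

fake_masks <- function(n_slices, w = 4) {
  structure(list(periosteal_region = array(1L, c(n_slices, w, w)),
                 cortical_mask = array(1L, c(n_slices, w, w)),
                 trabecular_roi = array(1L, c(n_slices, w, w)),
                 trabecular_bone = array(0L, c(n_slices, w, w)),
                 qc = data.frame(slice = seq_len(n_slices)),
                 voxel_size_mm = 0.00689),
            class = "compartment_masks")
}

test_that("VOI slice counts follow the percent frame arithmetic", {
  # scanner frame: 0.00689 mm voxels, L = 36.81 mm -> 0.018718%/slice;
  # a 4% VOI spans floor(4 / 0.018718) +/- 1 = 213 +/- 1 slices
  n <- 1400
  st <- binary_stack(array(1L, c(n, 4, 4)), 0.00689)
  fr <- build_frame(st, specimen_meta("s", "g", 36.81,
                                      distal_end_slice = n))
  voi <- extract_voi(fake_masks(n), fr, 81, 85, "trabecular")
  expect_lte(abs(length(voi$slices) - 213), 1)
  expect_true(all(voi$percent >= 81 & voi$percent < 85))
  expect_error(extract_voi(fake_masks(n), fr, 85, 85, "trabecular"),
               "lo_percent")
  expect_error(extract_voi(fake_masks(n), fr, 10, 14, "trabecular"),
               "out-of-range")
})

test_that("plate and rod fixtures give the canonical uPi values", {
  roi <- array(1L, c(40, 30, 40))
  p <- plate_volume(8, nx = 30, ny = 40, nz = 40)
  m <- trabecular_3d(p, roi, 1)
  expect_lt(abs(m$tb_th / 8 - 1), 0.05)
  expect_lt(abs(m$upi - 1), 0.1)
  rod <- rod_volume(6, n_slices = 40)
  roi_r <- array(1L, dim(rod))
  mr <- trabecular_3d(rod, roi_r, 1)
  expect_lt(abs(mr$tb_th / 12 - 1), 0.05)
  expect_lt(abs(mr$upi - 2), 0.2)
  # plate-model number: Tb.N = (BV/TV)/Tb.Th
  expect_equal(m$tb_n, m$bv_tv / m$tb_th, tolerance = 1e-12)
})

test_that("sphere surface-to-volume matches 3/r", {
  b <- ball_volume(20)
  roi <- array(1L, dim(b))
  m <- trabecular_3d(b, roi, 1)
  expect_lt(abs(m$bs_bv / (3 / 20) - 1), 0.03)
})

test_that("connectivity density reflects the Euler characteristic", {
  roi <- array(1L, c(33, 33, 33))
  ball <- ball_volume(8, n = 33)
  mb <- trabecular_3d(ball, roi, 1)
  expect_equal(mb$conn_d, 0)           # chi = 1
  tor <- torus_volume(8, 3, n = 33)
  mt <- trabecular_3d(tor, roi, 1)
  expect_equal(mt$conn_d, 1 / 33^3)    # chi = 0
  # Betti oracle on the same fixtures: chi = b0 - b1 + b2
  chi_ball <- euler_characteristic_3d(ball)
  b0 <- max(bonemorph:::label_components_3d(ball, 26))
  expect_equal(chi_ball, b0 - 0 + 0)
  chi_tor <- euler_characteristic_3d(tor)
  b0t <- max(bonemorph:::label_components_3d(tor, 26))
  expect_equal(chi_tor, b0t - 1 + 0)   # one loop, no cavity
})

test_that("plates score lower Tb.Pf than rods at matched volume fraction", {
  # convexity ordering, not absolute values
  roi <- array(1L, c(40, 36, 36))
  plates <- array(0L, c(40, 36, 36))
  for (k in 1:40) plates[k, , ] <- plate_lattice_mask(36, 36, 6, 18, 5)
  rods <- array(0L, c(40, 36, 36))
  rxy <- rod_lattice <- bonemorph:::rod_lattice_mask(36, 36, 5.85, 18)
  for (k in 1:40) rods[k, , ] <- rxy
  fp <- trabecular_3d(plates, roi, 1)
  fr <- trabecular_3d(rods, roi, 1)
  expect_lt(abs(fp$bv_tv - fr$bv_tv), 0.05)
  expect_lt(fp$tb_pf, fr$tb_pf)
})

test_that("3D estimators are exactly invariant to axis permutations", {
  b <- ball_volume(10)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    bp <- aperm(b, perm)
    expect_equal(surface_area_3d(bp), surface_area_3d(b), tolerance = 1e-9)
    expect_equal(local_thickness_mean(bp), local_thickness_mean(b),
                 tolerance = 1e-9)
    expect_identical(euler_characteristic_3d(bp), euler_characteristic_3d(b))
  }
})

test_that("3D estimators tolerate an oblique 30-degree rotation", {
  p <- array(0L, c(44, 44, 44))
  p[, 19:26, ] <- 1L    # plate t = 8
  th <- 30 * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3,
              byrow = TRUE)
  pr <- bonemorph:::rotate_volume(p, R, c(22.5, 22.5, 22.5))
  # clip to the central region where the rotated plate is not truncated
  core <- pr[13:32, , 13:32]
  expect_lt(abs(local_thickness_mean(core) / 8 - 1), 0.05)
})

test_that("uniform tube cortical VOI matches the annulus closed forms", {
  tube <- tube_volume(50, 40, 12)
  per <- array(0L, dim(tube))
  for (k in 1:12) per[k, , ] <- disc_mask(50, n = dim(tube)[2])
  m <- cortical_3d(tube, per, 1)
  expect_lt(abs(m$ct_th / 10 - 1), 0.03)
  expect_lt(abs(m$j / (pi * (50^4 - 40^4) / 2) - 1), 0.01)
  expect_equal(m$tt_ar, m$ct_ar + m$ma_ar, tolerance = 1e-9)
  expect_equal(m$ecc, 1, tolerance = 0.02)
})

test_that("elliptical tube eccentricity is 2 within 3%", {
  E <- ellipse_mask(60, 30)
  inner <- ellipse_mask(48, 24, n = nrow(E))
  tube <- array(0L, c(6, nrow(E), ncol(E)))
  per <- array(0L, c(6, nrow(E), ncol(E)))
  for (k in 1:6) { tube[k, , ] <- E * (1 - inner); per[k, , ] <- E }
  m <- cortical_3d(tube, per, 1)
  expect_equal(m$ecc, 2, tolerance = 0.03)
})

test_that("tube with varying radius averages per-slice J correctly", {
  n <- 16
  radii <- seq(34, 48, length.out = n)
  w <- 2 * 50 + 11
  tube <- array(0L, c(n, w, w)); per <- array(0L, c(n, w, w))
  for (k in 1:n) {
    tube[k, , ] <- annulus_mask(radii[k], radii[k] - 8, n = w)
    per[k, , ] <- disc_mask(radii[k], n = w)
  }
  m <- cortical_3d(tube, per, 1)
  j_expected <- mean(pi * (radii^4 - (radii - 8)^4) / 2)
  expect_lt(abs(m$j / j_expected - 1), 0.02)
})

test_that("VOI-averaged 2D area fraction equals 3D volume fraction exactly", {
  ph <- make_phantom(small_phantom(n = 16, decay = 0.02))
  masks <- segment_stack(ph$stack)
  fr <- build_frame(ph$stack, ph$meta)
  lo <- min(percent_of_slice(fr, 1:16)); hi <- 100
  voi <- extract_voi(masks, fr, lo, hi + 1e-9, "trabecular")
  m3 <- trabecular_3d(voi$bone, voi$roi, 0.02)
  # roi-weighted mean of per-slice BA/TA over the same voxel set
  ba <- vapply(seq_len(dim(voi$bone)[1]),
               function(i) sum(voi$bone[i, , ]), numeric(1))
  ta <- vapply(seq_len(dim(voi$roi)[1]),
               function(i) sum(voi$roi[i, , ]), numeric(1))
  expect_identical(m3$bv_tv, sum(ba) / sum(ta))
})
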