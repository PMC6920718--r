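# Per-slice 2D morphometry against closed forms and pixel-count oracles.

test_that("annulus cortical metrics match the closed forms", {
  ann <- annulus_mask(50, 40)
  per <- disc_mask(50, n = ncol(ann))
  cm <- cortical_metrics(ann, per, 1)
  expect_lt(abs(cm$ct_th_2d / 10 - 1), 0.02)
  expect_lt(abs(cm$ct_ar_2d / (pi * (50^2 - 40^2)) - 1), 0.01)
  expect_lt(abs(cm$ps_pm_2d / (2 * pi * 50) - 1), 0.01)
  expect_lt(abs(cm$ec_pm_2d / (2 * pi * 40) - 1), 0.01)
  # pixel-count oracle for areas, exact
  expect_equal(cm$ct_ar_2d, sum(ann))
  expect_equal(cm$tt_ar_2d, sum(per))
  expect_equal(cm$ma_ar_2d, sum(per) - sum(ann))
})

test_that("solid disc has zero marrow and unit area fraction", {
  d <- disc_mask(30)
  cm <- cortical_metrics(d, d, 0.5)
  expect_equal(cm$ma_ar_2d, 0)
  expect_equal(cm$ct_ar_2d, cm$tt_ar_2d)
  expect_equal(cm$ct_ar_frac, 1)
  expect_equal(cm$ec_pm_2d, 0)
})

test_that("nested squares give exact pixel-count areas", {
  m <- matrix(0, 120, 120)
  m[11:110, 11:110] <- 1          # outer 100 px square
  inner <- matrix(0, 120, 120)
  inner[31:90, 31:90] <- 1        # inner 60 px square
  cort <- m * (1 - inner)
  cm <- cortical_metrics(cort, m, 1)
  expect_equal(cm$ct_ar_2d, 100^2 - 60^2)
  expect_equal(cm$tt_ar_2d, 100^2)
  expect_equal(cm$ma_ar_2d, 60^2)
})

test_that("plate lattice recovers the analytic trabecular metrics", {
  # plates t = 10, p = 40, phase keeps plates interior; roi spans 5 periods
  L <- plate_lattice_mask(210, 160, 10, 40, phase_px = 5)
  roi <- matrix(0, 210, 160); roi[6:205, ] <- 1
  tm <- trabecular_metrics(L, roi, 1)
  expect_equal(tm$ba_ta, 0.25)
  expect_lt(abs(tm$tb_th_2d / 10 - 1), 0.03)
  expect_lt(abs(tm$tb_n_2d / (1 / 40) - 1), 0.03)
  expect_lt(abs(tm$tb_sp_2d / 30 - 1), 0.03)
  # plate-model identity to machine precision
  expect_equal(1 / tm$tb_n_2d - tm$tb_th_2d, tm$tb_sp_2d, tolerance = 1e-12)
})

test_that("degenerate trabecular inputs saturate or flag, never NaN", {
  roi <- matrix(1, 20, 20)
  tm <- trabecular_metrics(roi, roi, 1)
  expect_equal(tm$ba_ta, 1)
  tm0 <- trabecular_metrics(roi * 0, roi, 1)
  expect_equal(tm0$ba_ta, 0)
  expect_equal(tm0$tb_th_2d, 0)
  expect_equal(tm0$flag, "no-bone")
  expect_false(any(is.na(unlist(tm0[1:4]))))
  # checkerboard of 1 px squares counts exactly half
  cb <- (outer(1:40, 1:40, "+") %% 2 == 0) * 1
  expect_equal(trabecular_metrics(cb, matrix(1, 40, 40), 1)$ba_ta, 0.5)
})

test_that("local thickness model measures band width directly", {
  band <- matrix(0, 60, 80); band[26:35, ] <- 1
  roi <- matrix(1, 60, 80)
  tm <- trabecular_metrics(band, roi, 0.5, thickness_model = "local")
  expect_equal(tm$tb_th_2d, 10 * 0.5)
})

test_that("polar moment matches the stated formula and closed form", {
  # single pixel: self-moment only
  m <- matrix(0, 9, 9); m[5, 5] <- 1
  expect_equal(polar_moment(m, 2), 2^4 / 6)
  # annulus closed form within 1%
  ann <- annulus_mask(50, 40)
  expect_lt(abs(polar_moment(ann, 1) / (pi * (50^4 - 40^4) / 2) - 1), 0.01)
  # translation invariance
  big <- matrix(0, 140, 140)
  big[20 + seq_len(nrow(ann)), 5 + seq_len(ncol(ann))] <- ann
  expect_equal(polar_moment(big, 1), polar_moment(ann, 1))
  expect_equal(polar_moment(matrix(0, 5, 5), 1), 0)
})

test_that("eccentricity matches the moment ellipse and is invariant", {
  expect_equal(eccentricity(disc_mask(40)), 1, tolerance = 0.02)
  E <- ellipse_mask(60, 30)
  expect_equal(eccentricity(E), 2, tolerance = 0.03)
  # rotated copy: same value within 1%
  idx <- which(E > 0, arr.ind = TRUE)
  th <- 35 * pi / 180
  ctr <- (nrow(E) + 1) / 2
  rot <- cbind(round(ctr + cos(th) * (idx[, 1] - ctr) - sin(th) * (idx[, 2] - ctr)),
               round(ctr + sin(th) * (idx[, 1] - ctr) + cos(th) * (idx[, 2] - ctr)))
  ER <- matrix(0, nrow(E), ncol(E)); ER[rot] <- 1
  expect_lt(abs(eccentricity(ER) / eccentricity(E) - 1), 0.01)
  expect_error(eccentricity(matrix(c(0, 1, 0, 0, 1, 0, 0, 1, 0), 3)),
               "degenerate|collinear")
})

test_that("lengths, areas and J scale with voxel size as dimensioned", {
  ann <- annulus_mask(30, 22)
  per <- disc_mask(30, n = ncol(ann))
  c1 <- cortical_metrics(ann, per, 1)
  c2 <- cortical_metrics(ann, per, 2)
  expect_equal(c2$ct_th_2d, 2 * c1$ct_th_2d)
  expect_equal(c2$ps_pm_2d, 2 * c1$ps_pm_2d)
  expect_equal(c2$ct_ar_2d, 4 * c1$ct_ar_2d)
  expect_equal(polar_moment(ann, 2), 16 * polar_moment(ann, 1))
})

test_that("isoperimetric inequality holds on assorted sections", {
  for (m in list(disc_mask(25), ellipse_mask(40, 20),
                 {sq <- matrix(0, 60, 60); sq[11:50, 16:45] <- 1; sq})) {
    pm <- perimeter_2d(m)
    expect_gte(pm^2, 4 * pi * sum(m) * 0.999)
  }
})

test_that("the full slice metrics table is finite and flagged", {
  ph <- make_phantom(small_phantom(n = 10, decay = 0.03))
  masks <- segment_stack(ph$stack)
  fr <- build_frame(ph$stack, ph$meta)
  mt <- slice_metrics_table(masks, fr)
  expect_equal(nrow(mt), 10)
  num <- vapply(mt, is.numeric, logical(1))
  expect_false(any(!is.finite(as.matrix(mt[, num & names(num) != "ecc_2d"]))))
  expect_true(all(mt$tt_ar_2d >= mt$ct_ar_2d))
  expect_equal(mt$tt_ar_2d, mt$ct_ar_2d + mt$ma_ar_2d, tolerance = 1e-12)
})
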