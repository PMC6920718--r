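# Per-slice 2D morphometric parameters: trabecular BA/TA, thickness, number,
# separation; cortical areas, perimeters and thickness; second polar moment
# of area; periosteal eccentricity.

#' Trabecular 2D metrics for one slice
#'
#' BA/TA is the bone/ROI area ratio. Under the plate model
#' Tb.Th = 2 B.Ar / B.Pm (B.Pm from marching squares), Tb.N = (BA/TA)/Tb.Th
#' and Tb.Sp = 1/Tb.N - Tb.Th, so the classic identity holds by construction.
#' Under the local model Tb.Th is the mean inscribed-disc diameter over bone
#' and Tb.Sp the same statistic on background within the ROI.
#'
#' @param trabecular_bone,trabecular_roi 2D binary matrices with
#'   \code{trabecular_bone} inside \code{trabecular_roi}.
#' @param voxel_size_mm Pixel size in mm.
#' @param thickness_model "plate" (default) or "local".
#' @return A one-row data frame: ba_ta, tb_th_2d (mm), tb_n_2d (1/mm),
#'   tb_sp_2d (mm), flag.
#' @export
trabecular_metrics <- function(trabecular_bone, trabecular_roi, voxel_size_mm,
                               thickness_model = c("plate", "local")) {
  thickness_model <- match.arg(thickness_model)
  a <- voxel_size_mm
  bone <- (trabecular_bone > 0) & (trabecular_roi > 0)
  ta <- sum(trabecular_roi > 0)
  if (ta == 0)
    return(data.frame(ba_ta = 0, tb_th_2d = 0, tb_n_2d = 0, tb_sp_2d = 0,
                      flag = "empty-roi"))
  ba <- sum(bone)
  ba_ta <- ba / ta
  if (ba == 0)
    return(data.frame(ba_ta = 0, tb_th_2d = 0, tb_n_2d = 0, tb_sp_2d = 0,
                      flag = "no-bone"))
  if (thickness_model == "plate") {
    pm <- perimeter_2d(bone * 1)
    th <- if (pm > 0) 2 * ba * a / pm else 0
  } else {
    th <- local_thickness_mean(bone * 1) * a
  }
  if (th <= 0)
    return(data.frame(ba_ta = ba_ta, tb_th_2d = 0, tb_n_2d = 0, tb_sp_2d = 0,
                      flag = "degenerate-thickness"))
  n <- ba_ta / th
  sp <- if (thickness_model == "plate") 1 / n - th
        else local_thickness_mean(((trabecular_roi > 0) & !bone) * 1) * a
  data.frame(ba_ta = ba_ta, tb_th_2d = th, tb_n_2d = n, tb_sp_2d = sp,
             flag = "")
}

#' Cortical 2D metrics for one slice
#'
#' Areas by pixel count, perimeters by marching squares on the filled
#' periosteal region (Ps.Pm) and on the medullary region (Ec.Pm). The annular
#' model gives Ct.Th = 2 Ct.Ar / (Ps.Pm + Ec.Pm); the local model uses the
#' mean inscribed-disc diameter of the cortical mask.
#'
#' @param cortical_mask,periosteal_region 2D binary matrices with the cortex
#'   inside the periosteal region.
#' @param voxel_size_mm Pixel size in mm.
#' @param thickness_model "plate" (annular) or "local".
#' @return One-row data frame: ct_th_2d (mm), ct_ar_2d, tt_ar_2d, ma_ar_2d
#'   (mm^2), ct_ar_frac, ps_pm_2d, ec_pm_2d (mm), flag.
#' @export
cortical_metrics <- function(cortical_mask, periosteal_region, voxel_size_mm,
                             thickness_model = c("plate", "local")) {
  thickness_model <- match.arg(thickness_model)
  a <- voxel_size_mm
  ct_px <- sum(cortical_mask > 0)
  tt_px <- sum(periosteal_region > 0)
  if (ct_px == 0)
    return(data.frame(ct_th_2d = 0, ct_ar_2d = 0, tt_ar_2d = tt_px * a^2,
                      ma_ar_2d = tt_px * a^2, ct_ar_frac = 0, ps_pm_2d = 0,
                      ec_pm_2d = 0, flag = "empty-cortex"))
  ct_ar <- ct_px * a^2
  tt_ar <- tt_px * a^2
  ma_ar <- tt_ar - ct_ar
  ps_pm <- perimeter_2d(periosteal_region) * a
  medullary <- (periosteal_region > 0) & !(cortical_mask > 0)
  ec_pm <- if (any(medullary)) perimeter_2d(medullary * 1) * a else 0
  th <- if (thickness_model == "plate") {
    if (ps_pm + ec_pm > 0) 2 * ct_ar / (ps_pm + ec_pm) else 0
  } else local_thickness_mean((cortical_mask > 0) * 1) * a
  data.frame(ct_th_2d = th, ct_ar_2d = ct_ar, tt_ar_2d = tt_ar,
             ma_ar_2d = ma_ar, ct_ar_frac = ct_ar / tt_ar,
             ps_pm_2d = ps_pm, ec_pm_2d = ec_pm, flag = "")
}

#' Second polar moment of area of a binary section
#'
#' J = sum over pixels of ((x - xbar)^2 + (y - ybar)^2) a^2 per-pixel area
#' plus the per-pixel self moment a^4/6, about the section centroid, so a
#' single pixel gives exactly a^4/6 and the result is translation invariant.
#'
#' @param mask 2D binary matrix.
#' @param voxel_size_mm Pixel size in mm.
#' @return J in mm^4 (0 for an empty mask).
#' @export
polar_moment <- function(mask, voxel_size_mm) {
  a <- voxel_size_mm
  idx <- which(mask > 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(0)
  ctr <- colMeans(idx)
  r2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
  sum(r2) * a^4 + n * a^4 / 6
}

#' Eccentricity of a filled section
#'
#' Ratio of semimajor to semiminor axis of the moment-equivalent ellipse:
#' sqrt(lambda1 / lambda2) for the eigenvalues of the second central moment
#' matrix of the pixel coordinates. Always >= 1; rotation invariant.
#'
#' @param periosteal_region 2D binary matrix (filled region).
#' @return Eccentricity ratio.
#' @export
eccentricity <- function(periosteal_region) {
  idx <- which(periosteal_region > 0, arr.ind = TRUE)
  if (nrow(idx) < 3)
    stop("validation error: eccentricity needs at least 3 pixels")
  cc <- stats::cov(idx)
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-12)
    stop("validation error: degenerate (collinear) region")
  sqrt(ev[1] / ev[2])
}

#' Full per-slice metrics table for a segmented stack
#'
#' Computes every 2D parameter on every slice and attaches the percent bone
#' length from the specimen frame, producing the native-resolution
#' morphometric distributions.
#'
#' @param masks A \code{compartment_masks}.
#' @param frame A \code{specimen_frame}.
#' @param thickness_model "plate" or "local".
#' @return Data frame with one row per slice: slice, percent, all trabecular
#'   and cortical fields, j_2d, ecc_2d and flags.
#' @export
slice_metrics_table <- function(masks, frame,
                                thickness_model = c("plate", "local")) {
  thickness_model <- match.arg(thickness_model)
  stopifnot(inherits(masks, "compartment_masks"),
            inherits(frame, "specimen_frame"))
  a <- masks$voxel_size_mm
  n <- dim(masks$cortical_mask)[1]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tb <- trabecular_metrics(masks$trabecular_bone[i, , ],
                             masks$trabecular_roi[i, , ], a, thickness_model)
    ct <- cortical_metrics(masks$cortical_mask[i, , ],
                           masks$periosteal_region[i, , ], a, thickness_model)
    per <- masks$periosteal_region[i, , ]
    j <- polar_moment(masks$cortical_mask[i, , ], a)
    ecc <- if (sum(per) >= 3) {
      e <- try(eccentricity(per), silent = TRUE)
      if (inherits(e, "try-error")) NA_real_ else e
    } else NA_real_
    flags <- paste(c(if (nzchar(tb$flag)) tb$flag,
                     if (nzchar(ct$flag)) ct$flag), collapse = ";")
    rows[[i]] <- cbind(data.frame(slice = i,
                                  percent = percent_of_slice(frame, i)),
                       tb[setdiff(names(tb), "flag")],
                       ct[setdiff(names(ct), "flag")],
                       data.frame(j_2d = j, ecc_2d = ecc, flag = flags))
  }
  do.call(rbind, rows)
}
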