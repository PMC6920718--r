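# Per-slice separation of bone into cortical shell, trabecular ROI and
# trabecular bone, with periosteal/endocortical regions derived by
# morphological closing and hole filling (EBImage).

disc_brush <- function(radius) {
  if (radius < 1) return(matrix(1, 1, 1))
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(mask * 0)
  tab <- tabulate(lab[lab > 0])
  (lab == which.max(tab)) * 1
}

#' Segment one slice into cortical and trabecular compartments
#'
#' The periosteal region is the hole-filled morphological closing of the
#' largest connected foreground component. Bone connected to the periosteal
#' boundary is cortical; thin trabecular bridges onto the cortex are detached
#' by an erosion of depth \code{bridge_cut_px} before the connectivity test.
#' The trabecular ROI is the medullary region minus a guard band of width
#' \code{guard_px} along the endocortical boundary, and trabecular bone is
#' foreground inside that ROI.
#'
#' @param slice_mask 2D binary matrix (may be empty; gap slices are allowed).
#' @param closing_radius_px Radius of the closing disc bridging cortical
#'   breaches.
#' @param bridge_cut_px Erosion depth detaching trabeculae that touch the
#'   cortex before cortical bone is identified by connectivity.
#' @param guard_px Width of the endocortical guard band excluded from the
#'   trabecular ROI; defaults to the closing radius.
#' @param open_coverage_min Minimum fraction of the periosteal boundary that
#'   must be adjacent to cortical bone; below it the slice is flagged as an
#'   open cortex.
#' @return A list with binary matrices \code{periosteal_region},
#'   \code{cortical_mask}, \code{trabecular_roi}, \code{trabecular_bone} and
#'   a logical \code{open_cortex} QC flag.
#' @export
segment_slice <- function(slice_mask, closing_radius_px = 5,
                          bridge_cut_px = 2, guard_px = closing_radius_px,
                          open_coverage_min = 0.95) {
  f0 <- (slice_mask > 0) * 1
  empty <- f0 * 0
  if (sum(f0) == 0)
    return(list(periosteal_region = empty, cortical_mask = empty,
                trabecular_roi = empty, trabecular_bone = empty,
                open_cortex = FALSE))
  # pad with background so border-clamped morphology cannot fabricate
  # foreground at the image edge
  pad <- as.integer(closing_radius_px + guard_px + 2)
  d0 <- dim(f0)
  f <- matrix(0, d0[1] + 2 * pad, d0[2] + 2 * pad)
  f[pad + seq_len(d0[1]), pad + seq_len(d0[2])] <- f0
  main <- largest_component(f)
  closed <- EBImage::closing(main, disc_brush(closing_radius_px))
  per <- EBImage::fillHull(closed)
  boundary <- per - EBImage::erode(per, disc_brush(1))
  # cortical bone: components of the bridge-cut foreground touching the
  # periosteal boundary, grown back by the cut depth, intersected with bone
  if (bridge_cut_px > 0) {
    core <- EBImage::erode(f, disc_brush(bridge_cut_px))
  } else core <- f
  cortical <- empty
  # grow the seed back onto the bone by geodesic reconstruction of bounded
  # depth, recovering the eroded rim without re-crossing cut bridges
  reconstruct <- function(seed, depth) {
    rec <- seed
    b1 <- disc_brush(1)
    for (it in seq_len(depth)) rec <- EBImage::dilate(rec, b1) * f
    rec
  }
  if (sum(core) > 0) {
    lab <- EBImage::bwlabel(core)
    near_boundary <- EBImage::dilate(boundary, disc_brush(bridge_cut_px + 2))
    touch <- sort(unique(lab[lab > 0 & near_boundary > 0]))
    if (length(touch) > 0) {
      seed <- (array(lab %in% touch, dim(lab))) * 1
      cortical <- reconstruct(seed, bridge_cut_px + 2)
    }
  }
  if (sum(cortical) == 0) {
    # no erodible core (very thin shell): fall back to bone on the boundary
    cortical <- reconstruct(f * EBImage::dilate(boundary, disc_brush(1)),
                            bridge_cut_px + 2)
  }
  medullary <- pmax(per - cortical, 0)
  excl <- EBImage::dilate(pmax(cortical, 1 - per), disc_brush(guard_px))
  roi <- (medullary > 0 & excl == 0) * 1
  trab <- f * roi
  covered <- if (sum(boundary) > 0) {
    near_cort <- EBImage::dilate(cortical, disc_brush(3))
    sum(boundary > 0 & near_cort > 0) / sum(boundary > 0)
  } else 1
  # an open cortex leaves no enclosed cavity after closing while the section
  # is strongly non-convex (an open ring); a solid section is convex-ish
  cavity <- sum(per) - sum(closed > 0)
  open_ring <- FALSE
  if (cavity < 0.01 * sum(per)) {
    idx <- which(per > 0, arr.ind = TRUE)
    h <- grDevices::chull(idx)
    hx <- idx[h, 1]; hy <- idx[h, 2]
    hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    open_ring <- hull_area > 1.2 * sum(per)
  }
  crop <- function(m)
    as.matrix(m)[pad + seq_len(d0[1]), pad + seq_len(d0[2])] * 1
  list(periosteal_region = crop(per),
       cortical_mask = crop(cortical),
       trabecular_roi = crop(roi),
       trabecular_bone = crop(trab),
       open_cortex = covered < open_coverage_min || open_ring)
}

#' Segment every slice of a stack
#'
#' Applies \code{\link{segment_slice}} slice-wise and collects per-slice QC
#' flags. If more than \code{max_flag_fraction} of the slices containing
#' foreground are flagged as open cortex, segmentation fails with the list of
#' offending slices.
#'
#' @param stack An aligned \code{binary_stack}.
#' @param closing_radius_px,bridge_cut_px,guard_px,open_coverage_min Passed to
#'   \code{\link{segment_slice}}.
#' @param max_flag_fraction Tolerated fraction of flagged in-range slices.
#' @return An object of class \code{compartment_masks}: 3D arrays
#'   \code{periosteal_region}, \code{cortical_mask}, \code{trabecular_roi},
#'   \code{trabecular_bone} plus a QC data frame (\code{qc}).
#' @export
segment_stack <- function(stack, closing_radius_px = 5, bridge_cut_px = 2,
                          guard_px = closing_radius_px,
                          open_coverage_min = 0.95,
                          max_flag_fraction = 0.2) {
  stopifnot(inherits(stack, "binary_stack"))
  d <- dim(stack$voxels)
  out <- list(periosteal_region = array(0L, d), cortical_mask = array(0L, d),
              trabecular_roi = array(0L, d), trabecular_bone = array(0L, d))
  flags <- logical(d[1]); has_fg <- logical(d[1])
  for (i in seq_len(d[1])) {
    sl <- stack$voxels[i, , ]
    has_fg[i] <- sum(sl) > 0
    s <- segment_slice(sl, closing_radius_px, bridge_cut_px, guard_px,
                       open_coverage_min)
    out$periosteal_region[i, , ] <- s$periosteal_region
    out$cortical_mask[i, , ] <- s$cortical_mask
    out$trabecular_roi[i, , ] <- s$trabecular_roi
    out$trabecular_bone[i, , ] <- s$trabecular_bone
    flags[i] <- s$open_cortex
  }
  if (any(has_fg) && mean(flags[has_fg]) > max_flag_fraction)
    stop("segmentation failure: open cortex flagged on slices ",
         paste(which(flags), collapse = ", "))
  structure(c(out, list(qc = data.frame(slice = seq_len(d[1]),
                                        has_foreground = has_fg,
                                        open_cortex = flags),
                        voxel_size_mm = stack$voxel_size_mm)),
            class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat(sprintf("<compartment_masks> %d slices; cortical %d vx, trabecular %d vx, flagged %d\n",
              dim(x$cortical_mask)[1], sum(x$cortical_mask),
              sum(x$trabecular_bone), sum(x$qc$open_cortex)))
  invisible(x)
}
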