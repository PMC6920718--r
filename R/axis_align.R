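# Principal-axis alignment of the shaft centreline with the slice axis, and
# the percent-bone-length coordinate frame shared by all downstream modules.

foreground_principal_axis <- function(vox) {
  idx <- which(vox > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("alignment error: empty foreground")
  if (length(unique(idx[, 1])) < 2L)
    stop("alignment error: degenerate foreground (single slice plane)")
  cc <- stats::cov(idx)
  e <- eigen(cc, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (v[1] < 0) v <- -v        # orient towards increasing slice index
  v / sqrt(sum(v^2))
}

#' Angle between the foreground principal axis and the slice axis
#'
#' @param stack A \code{binary_stack}.
#' @return Angle in degrees.
#' @export
principal_axis_angle <- function(stack) {
  v <- foreground_principal_axis(stack$voxels)
  acos(min(1, abs(v[1]))) * 180 / pi
}

rotation_matrix_from_to <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # 180 degrees: rotate about any axis orthogonal to a
    w <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- w - sum(w * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

# Rigid rotation of a volume about the foreground centroid with trilinear
# interpolation, sampled on the same grid.
rotate_volume <- function(vox, R, center, threshold = 0.5) {
  d <- dim(vox)
  out_idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                   k = seq_len(d[3])))
  src <- sweep(out_idx, 2, center) %*% t(R)    # inverse map: R is target->source
  src <- sweep(src, 2, center, "+")
  i0 <- floor(src)
  fr <- src - i0
  acc <- numeric(nrow(src))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    ii <- i0[, 1] + di; jj <- i0[, 2] + dj; kk <- i0[, 3] + dk
    w <- (if (di == 1) fr[, 1] else 1 - fr[, 1]) *
         (if (dj == 1) fr[, 2] else 1 - fr[, 2]) *
         (if (dk == 1) fr[, 3] else 1 - fr[, 3])
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3] &
      w > 0
    if (!any(ok)) next
    li <- ii[ok] + (jj[ok] - 1) * d[1] + (kk[ok] - 1) * d[1] * d[2]
    acc[ok] <- acc[ok] + w[ok] * vox[li]
  }
  array(as.integer(acc >= threshold), d)
}

#' Align the shaft centreline with the slice axis
#'
#' Rotates the volume rigidly so that the first principal axis of the
#' foreground (the shaft centreline of a long-bone segment) is parallel to
#' the slice axis, replacing interactive reorientation with a deterministic
#' surrogate. Trilinear interpolation followed by re-binarization at 0.5
#' keeps the foreground volume approximately conserved. The rotation is
#' iterated (up to \code{max_iter}) because re-binarization can leave a small
#' residual tilt after a single pass. The method presumes an elongated
#' volume (shaft longer than wide); for short stubby volumes the first
#' principal axis is not the shaft centreline and a warning is raised when
#' the target tolerance is not reached.
#'
#' @param stack A \code{binary_stack} with non-empty foreground.
#' @param tol_deg Target angular deviation in degrees.
#' @param max_iter Maximum alignment passes.
#' @return The aligned \code{binary_stack}, with attribute
#'   \code{achieved_angle_deg}.
#' @export
align_to_principal_axis <- function(stack, tol_deg = 1, max_iter = 3) {
  stopifnot(inherits(stack, "binary_stack"))
  vox <- stack$voxels
  for (it in seq_len(max_iter)) {
    v <- foreground_principal_axis(vox)
    ang <- acos(min(1, abs(v[1]))) * 180 / pi
    if (ang <= tol_deg * 0.25 && it > 1) break
    if (ang <= 1e-6) break
    R <- rotation_matrix_from_to(c(1, 0, 0), v)  # target axis -> current axis
    ctr <- colMeans(which(vox > 0, arr.ind = TRUE))
    vox <- rotate_volume(vox, R, ctr)
    if (sum(vox) == 0) stop("alignment error: rotation emptied the volume")
    v2 <- foreground_principal_axis(vox)
    if (acos(min(1, abs(v2[1]))) * 180 / pi <= tol_deg) break
  }
  out <- binary_stack(vox, stack$voxel_size_mm, stack$slice_axis_direction)
  ang <- principal_axis_angle(out)
  if (ang > tol_deg)
    warning("alignment did not converge (principal axis ",
            sprintf("%.1f", ang), " deg off the slice axis); ",
            "principal-axis alignment assumes the scanned segment is ",
            "longer than it is wide")
  attr(out, "achieved_angle_deg") <- ang
  out
}

#' Percent-bone-length coordinate frame
#'
#' Maps slice indices to percent of total bone length, measured from the
#' proximal end so that the distal condyle end is 100\%. Moving proximally by
#' one slice decreases percent by 100 * voxel_size_mm / L.
#'
#' @param stack A \code{binary_stack}.
#' @param meta A \code{specimen_meta}; \code{bone_length_mm} must be set. If
#'   \code{distal_end_slice} is NA, the most distal foreground slice is used.
#' @return An object of class \code{specimen_frame}.
#' @export
build_frame <- function(stack, meta) {
  stopifnot(inherits(stack, "binary_stack"), inherits(meta, "specimen_meta"))
  if (is.null(meta$bone_length_mm) || is.na(meta$bone_length_mm))
    stop("configuration error: bone_length_mm unset")
  n <- dim(stack$voxels)[1]
  des <- meta$distal_end_slice
  if (is.na(des)) {
    fg <- which(apply(stack$voxels, 1, sum) > 0)
    if (length(fg) == 0) stop("validation error: empty volume")
    des <- if (stack$slice_axis_direction == "distal_increasing")
      max(fg) else min(fg)
  }
  if (des < 1 || des > n)
    stop("configuration error: distal_end_slice outside stack bounds")
  structure(list(distal_end_slice = as.integer(des),
                 bone_length_mm = meta$bone_length_mm,
                 voxel_size_mm = stack$voxel_size_mm,
                 slice_axis_direction = stack$slice_axis_direction,
                 n_slices = n),
            class = "specimen_frame")
}

#' @export
print.specimen_frame <- function(x, ...) {
  cat(sprintf("<specimen_frame> L = %.2f mm, voxel %.5f mm, distal end at slice %d/%d (%s)\n",
              x$bone_length_mm, x$voxel_size_mm, x$distal_end_slice,
              x$n_slices, x$slice_axis_direction))
  invisible(x)
}

#' Percent bone length of a slice index
#'
#' @param frame A \code{specimen_frame}.
#' @param slice Slice index (vectorized).
#' @return Percent bone length; exactly 100 at the distal end slice.
#' @export
percent_of_slice <- function(frame, slice) {
  step <- 100 * frame$voxel_size_mm / frame$bone_length_mm
  distal_dist <- if (frame$slice_axis_direction == "distal_increasing")
    frame$distal_end_slice - slice else slice - frame$distal_end_slice
  100 - distal_dist * step
}

#' Nearest slice index at a percent bone length
#'
#' Inverse of \code{\link{percent_of_slice}}, rounded to the nearest slice.
#'
#' @param frame A \code{specimen_frame}.
#' @param percent Percent bone length (vectorized).
#' @export
slice_at_percent <- function(frame, percent) {
  step <- 100 * frame$voxel_size_mm / frame$bone_length_mm
  k <- (100 - percent) / step
  if (frame$slice_axis_direction == "distal_increasing")
    as.integer(round(frame$distal_end_slice - k))
  else as.integer(round(frame$distal_end_slice + k))
}
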