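#' Binarized image stack container
#'
#' A \code{binary_stack} holds an aligned, binarized micro-CT volume as a
#' 3D array indexed (slice, row, col), together with the isotropic voxel
#' size and the direction in which slice index increases along the bone.
#' Any non-zero voxel is foreground (8-bit binarized exports use 255).
#'
#' @param voxels 3D array; coerced to 0/1 integer.
#' @param voxel_size_mm Positive isotropic voxel size in mm. The scanner
#'   protocol this package targets uses 6.89 um voxels, so the default is
#'   0.00689 mm.
#' @param slice_axis_direction "distal_increasing" (higher slice index is
#'   more distal) or "proximal_increasing".
#' @return An object of class \code{binary_stack}.
#' @export
binary_stack <- function(voxels, voxel_size_mm = 0.00689,
                         slice_axis_direction = c("distal_increasing",
                                                  "proximal_increasing")) {
  slice_axis_direction <- match.arg(slice_axis_direction)
  if (length(dim(voxels)) != 3L)
    stop("format error: voxels must be a 3D array (slice, row, col)")
  if (dim(voxels)[1] < 1L)
    stop("validation error: stack must contain at least one slice")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("validation error: voxel_size_mm must be a positive scalar")
  v <- array(as.integer(voxels > 0), dim(voxels))
  structure(list(voxels = v, voxel_size_mm = voxel_size_mm,
                 slice_axis_direction = slice_axis_direction),
            class = "binary_stack")
}

#' @export
print.binary_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_stack> %d slices x %d x %d, voxel %.5f mm, %s; foreground %d vx\n",
              d[1], d[2], d[3], x$voxel_size_mm, x$slice_axis_direction,
              sum(x$voxels)))
  invisible(x)
}

#' @export
dim.binary_stack <- function(x) dim(x$voxels)

#' Per-specimen metadata
#'
#' @param specimen_id,group Identifier strings.
#' @param bone_length_mm Total bone length L in mm (caliper measurement).
#' @param growth_plate_slice Slice index of the growth-plate reference level
#'   (most proximal slice with a continuous chondrocyte seam), or NA if unset.
#' @param distal_end_slice Slice index of the distal end (maps to 100\% bone
#'   length), or NA to let it default to the most distal foreground slice.
#' @return An object of class \code{specimen_meta}.
#' @export
specimen_meta <- function(specimen_id, group = "unassigned", bone_length_mm,
                          growth_plate_slice = NA_integer_,
                          distal_end_slice = NA_integer_) {
  if (missing(bone_length_mm) || is.null(bone_length_mm) ||
      is.na(bone_length_mm))
    stop("configuration error: missing manifest key 'bone_length_mm'")
  if (bone_length_mm <= 0)
    stop("validation error: bone_length_mm must be > 0")
  structure(list(specimen_id = as.character(specimen_id),
                 group = as.character(group),
                 bone_length_mm = bone_length_mm,
                 growth_plate_slice = as.integer(growth_plate_slice),
                 distal_end_slice = as.integer(distal_end_slice)),
            class = "specimen_meta")
}

MANIFEST_REQUIRED <- c("specimen_id", "voxel_size_mm", "bone_length_mm")

#' Read a specimen manifest
#'
#' The manifest is a YAML key-value file carrying specimen_id, group,
#' voxel_size_mm, bone_length_mm, growth_plate_slice, distal_end_slice and
#' slice_axis_direction.
#'
#' @param path Path to the manifest file.
#' @return A list with elements \code{meta} (\code{specimen_meta}),
#'   \code{voxel_size_mm} and \code{slice_axis_direction}.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("configuration error: manifest not found: ", path)
  m <- yaml::read_yaml(path)
  missing_keys <- setdiff(MANIFEST_REQUIRED, names(m))
  if (length(missing_keys) > 0)
    stop("configuration error: missing manifest key '",
         paste(missing_keys, collapse = "', '"), "'")
  list(meta = specimen_meta(
         specimen_id = m$specimen_id,
         group = if (is.null(m$group)) "unassigned" else m$group,
         bone_length_mm = m$bone_length_mm,
         growth_plate_slice = if (is.null(m$growth_plate_slice)) NA_integer_
                              else m$growth_plate_slice,
         distal_end_slice = if (is.null(m$distal_end_slice)) NA_integer_
                            else m$distal_end_slice),
       voxel_size_mm = m$voxel_size_mm,
       slice_axis_direction = if (is.null(m$slice_axis_direction))
         "distal_increasing" else m$slice_axis_direction)
}

#' Write a specimen manifest
#'
#' @param meta A \code{specimen_meta}.
#' @param voxel_size_mm Voxel size recorded with the stack.
#' @param slice_axis_direction Slice axis convention.
#' @param path Output file path.
#' @export
write_manifest <- function(meta, voxel_size_mm, slice_axis_direction, path) {
  m <- list(specimen_id = meta$specimen_id, group = meta$group,
            voxel_size_mm = voxel_size_mm,
            bone_length_mm = meta$bone_length_mm,
            slice_axis_direction = slice_axis_direction)
  if (!is.na(meta$growth_plate_slice))
    m$growth_plate_slice <- meta$growth_plate_slice
  if (!is.na(meta$distal_end_slice))
    m$distal_end_slice <- meta$distal_end_slice
  yaml::write_yaml(m, path)
  invisible(path)
}

read_image_2d <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("format error: unsupported slice image format '", ext,
         "' (use multi-page TIFF or PNG sequences)"))
  if (length(dim(img)) == 3L) img <- img[, , 1]   # collapse channels
  if (length(dim(img)) != 2L)
    stop("format error: slice image is not a 2D page: ", path)
  img
}

#' Read a binarized stack with its manifest
#'
#' \code{path} may be a multi-page TIFF file or a directory of numbered
#' single-slice PNG/TIFF images (slice order follows lexicographic filename
#' order, matching numbered scanner exports). Any pixel > 0 is foreground.
#'
#' @param path Stack file or slice directory.
#' @param manifest Path to the YAML manifest (see \code{\link{read_manifest}}).
#' @return A list with elements \code{stack} (\code{binary_stack}) and
#'   \code{meta} (\code{specimen_meta}).
#' @export
read_stack <- function(path, manifest) {
  mf <- read_manifest(manifest)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0)
      stop("format error: no PNG/TIFF slices found in ", path)
    pages <- lapply(files, read_image_2d)
  } else if (file.exists(path)) {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("tif", "tiff"))
      stop("format error: single-file stacks must be multi-page TIFF")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]
      if (length(dim(p)) != 2L) stop("format error: non-2D TIFF page")
      p
    })
  } else stop("I/O error: path does not exist: ", path)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("format error: inconsistent slice dimensions across pages")
  vox <- array(0L, c(length(pages), dims[1, 1], dims[2, 1]))
  for (i in seq_along(pages)) vox[i, , ] <- as.integer(pages[[i]] > 0)
  st <- binary_stack(vox, voxel_size_mm = mf$voxel_size_mm,
                     slice_axis_direction = mf$slice_axis_direction)
  nb <- check_slice_bounds(st, mf$meta)
  list(stack = st, meta = nb)
}

check_slice_bounds <- function(stack, meta) {
  n <- dim(stack$voxels)[1]
  for (f in c("growth_plate_slice", "distal_end_slice")) {
    v <- meta[[f]]
    if (!is.na(v) && (v < 1L || v > n))
      stop("validation error: ", f, " (", v, ") outside stack bounds [1, ",
           n, "]")
  }
  meta
}

#' Write a binarized stack
#'
#' Writes either a single multi-page TIFF (path ending .tif/.tiff) or a
#' directory of numbered PNG slices. Round-trips voxel-for-voxel with
#' \code{\link{read_stack}}.
#'
#' @param stack A \code{binary_stack}.
#' @param path Output .tif file or directory (created if needed).
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "binary_stack"))
  v <- stack$voxels
  n <- dim(v)[1]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- lapply(seq_len(n), function(i) v[i, , ] * 1.0)
    ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 8), silent = TRUE)
    if (inherits(ok, "try-error")) stop("I/O error: cannot write ", path)
  } else {
    if (!dir.exists(path)) {
      ok <- try(dir.create(path, recursive = TRUE), silent = TRUE)
      if (inherits(ok, "try-error") || !dir.exists(path))
        stop("I/O error: cannot create directory ", path)
    }
    for (i in seq_len(n))
      png::writePNG(v[i, , ] * 1.0,
                    file.path(path, sprintf("s%05d.png", i)))
  }
  invisible(path)
}
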