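# Morphometric distributions on the percent-bone-length axis: interpolation
# of native per-slice values onto the common 1% grid, Trabecular Extent
# (Tb.E), and group difference profiles.

#' Default analysis grids
#'
#' Trabecular distributions cover 60 to 100 percent bone length, cortical
#' distributions 40 to 80 percent, both at a 1 percent step.
#' @param compartment "trabecular" or "cortical".
#' @return Numeric grid of percent values.
#' @export
default_grid <- function(compartment = c("trabecular", "cortical")) {
  compartment <- match.arg(compartment)
  if (compartment == "trabecular") seq(60, 100, by = 1) else seq(40, 80, by = 1)
}

#' Interpolate a native per-slice distribution onto a percent grid
#'
#' Native samples live at the percent positions of their slices; a cubic
#' spline through them is evaluated at the grid points. No extrapolation is
#' performed: every grid point must be inside the covered native range.
#'
#' @param metrics_table Per-slice table from \code{\link{slice_metrics_table}}
#'   (needs columns \code{percent} and the requested parameter), or any data
#'   frame with those columns.
#' @param parameter Column name to interpolate (e.g. "ba_ta").
#' @param grid Percent grid (default 1\% trabecular grid).
#' @param range_percent Optional (lo, hi) restriction of the native samples
#'   used, e.g. c(60, 100).
#' @param specimen_id Identifier attached to the profile.
#' @return A \code{morph_profile}: data frame (percent, value) with
#'   attributes \code{parameter} and \code{specimen_id}.
#' @export
build_profile <- function(metrics_table, parameter, grid = default_grid(),
                          range_percent = NULL, specimen_id = "specimen") {
  if (!parameter %in% names(metrics_table))
    stop("configuration error: no column '", parameter, "' in metrics table")
  x <- metrics_table$percent
  y <- metrics_table[[parameter]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!is.null(range_percent)) {
    keep <- x >= range_percent[1] & x <= range_percent[2]
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 4) stop("validation error: too few native samples")
  o <- order(x); x <- x[o]; y <- y[o]
  if (min(grid) < min(x) - 1e-9 || max(grid) > max(x) + 1e-9)
    stop("out-of-range error: grid spans [", min(grid), ", ", max(grid),
         "] but native samples cover [", round(min(x), 3), ", ",
         round(max(x), 3), "]")
  v <- stats::spline(x, y, xout = grid, method = "fmm", ties = mean)$y
  structure(data.frame(percent = grid, value = v),
            parameter = parameter, specimen_id = specimen_id,
            class = c("morph_profile", "data.frame"))
}

#' Trabecular Extent (Tb.E)
#'
#' Distance that the distal trabecular structure extends into the medullary
#' cavity, measured proximally from the growth-plate reference level along
#' the native-resolution BA/TA distribution. For each threshold the first
#' crossing (scanning proximally, i.e. towards decreasing percent) where
#' BA/TA equals the threshold is located by linear interpolation between the
#' bracketing native samples; Tb.E(threshold) is the distance from the
#' reference to that crossing in mm. Tb.E_Abs is the distance to the most
#' proximal native sample with BA/TA > 0 within the covered range.
#'
#' Thresholds never reached (BA/TA stays above through the whole range) are
#' censored at the full covered distance; thresholds above BA/TA at the
#' reference level give 0. Both carry flags instead of NA so group tables
#' stay rectangular.
#'
#' @param percent,ba_ta Native-resolution BA/TA samples (per slice).
#' @param bone_length_mm Total bone length L in mm.
#' @param reference_percent Growth-plate level in percent bone length.
#' @param thresholds BA/TA thresholds, default c(0.30, 0.20, 0.10, 0).
#' @param range_lo Proximal end of the analysed range in percent (default 60).
#' @return A data frame with one row per threshold (threshold,
#'   crossing_percent, tbe_mm, censored, flag) and attributes
#'   \code{tbe_abs_mm} and \code{reference_percent}.
#' @export
trabecular_extent <- function(percent, ba_ta, bone_length_mm,
                              reference_percent,
                              thresholds = c(0.30, 0.20, 0.10, 0),
                              range_lo = 60) {
  ok <- is.finite(percent) & is.finite(ba_ta) & percent >= range_lo
  x <- percent[ok]; v <- ba_ta[ok]
  if (length(x) < 2) stop("validation error: too few samples for Tb.E")
  if (reference_percent > max(x) + 1e-9 || reference_percent < min(x) - 1e-9)
    stop("out-of-range error: reference_percent outside covered range")
  # value at the reference by linear interpolation on the native samples
  oi <- order(x)
  v_ref <- stats::approx(x[oi], v[oi], xout = reference_percent,
                         ties = "ordered")$y
  o <- order(x, decreasing = TRUE)   # scan proximally from high percent
  x <- x[o]; v <- v[o]
  scan <- x <= reference_percent + 1e-12
  xs <- c(reference_percent, x[scan])
  vs <- c(v_ref, v[scan])
  dup <- duplicated(xs)
  xs <- xs[!dup]; vs <- vs[!dup]
  mm_per_pct <- bone_length_mm / 100
  full_mm <- (reference_percent - min(xs)) * mm_per_pct
  rows <- lapply(thresholds, function(thr) {
    if (vs[1] < thr)
      return(data.frame(threshold = thr, crossing_percent = reference_percent,
                        tbe_mm = 0, censored = FALSE,
                        flag = "below-at-reference"))
    k <- which(vs[-length(vs)] >= thr & vs[-1] < thr)
    hit <- which(vs <= thr)   # sample exactly at/below the threshold
    if (length(k) == 0 && length(hit) == 0)
      return(data.frame(threshold = thr, crossing_percent = min(xs),
                        tbe_mm = full_mm, censored = TRUE, flag = "censored"))
    if (length(k) == 0) {
      cp <- xs[min(hit)]
    } else {
      k <- min(k)
      if (length(hit) > 0 && min(hit) <= k) {
        cp <- xs[min(hit)]
      } else {
        t <- (vs[k] - thr) / (vs[k] - vs[k + 1])
        cp <- xs[k] + t * (xs[k + 1] - xs[k])
      }
    }
    data.frame(threshold = thr, crossing_percent = cp,
               tbe_mm = (reference_percent - cp) * mm_per_pct,
               censored = FALSE, flag = "")
  })
  out <- do.call(rbind, rows)
  pos <- xs[vs > 0]
  attr(out, "tbe_abs_mm") <- if (length(pos) > 0)
    (reference_percent - min(pos)) * mm_per_pct else 0
  attr(out, "reference_percent") <- reference_percent
  out
}

#' Mean difference between two groups of profiles
#'
#' @param profiles_a,profiles_b Lists of \code{morph_profile}s (or data
#'   frames with percent/value) on the same grid; a is the reference group.
#' @return Data frame: percent, mean_a, mean_b, diff (mean_a - mean_b),
#'   abs_diff, sign.
#' @export
difference_profile <- function(profiles_a, profiles_b) {
  stack_vals <- function(ps) {
    g <- ps[[1]]$percent
    for (p in ps)
      if (!isTRUE(all.equal(p$percent, g)))
        stop("validation error: profiles are not on a shared grid")
    list(grid = g, m = vapply(ps, function(p) p$value, numeric(length(g))))
  }
  a <- stack_vals(profiles_a); b <- stack_vals(profiles_b)
  if (!isTRUE(all.equal(a$grid, b$grid)))
    stop("validation error: groups are on different grids")
  ma <- rowMeans(as.matrix(a$m)); mb <- rowMeans(as.matrix(b$m))
  d <- ma - mb
  data.frame(percent = a$grid, mean_a = ma, mean_b = mb, diff = d,
             abs_diff = abs(d),
             sign = ifelse(d > 0, "positive", ifelse(d < 0, "negative",
                                                     "zero")))
}
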