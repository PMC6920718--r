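# Low-level geometric primitives shared by the 2D and 3D morphometry code:
# separable Gaussian smoothing, exact Euclidean distance transforms,
# iso-surface / iso-contour measurement and local (inscribed-disc/sphere)
# thickness. All operate on plain R arrays in pixel units; callers apply the
# voxel size.

gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution with reflected (mirror) boundaries. Reflection keeps flat
# regions flat up to the array edge, so structures that run out of the field
# of view generate no spurious iso-surface there.
conv1d_reflect <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  n <- length(x)
  if (n == 1L) return(x)
  r <- min(r, n - 1L)
  kk <- if (r < (length(k) - 1L) / 2L) {
    mid <- (length(k) + 1L) / 2L
    ks <- k[(mid - r):(mid + r)]
    ks / sum(ks)
  } else k
  xp <- c(rev(x[seq_len(r)]), x, rev(x[(n - r + 1L):n]))
  as.numeric(stats::filter(xp, kk, sides = 2))[(r + 1L):(r + n)]
}

smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gauss_kernel(sigma)
  m <- apply(m, 2, conv1d_reflect, k = k)
  t(apply(m, 1, conv1d_reflect, k = k))
}

smooth3d <- function(v, sigma) {
  if (sigma <= 0) return(v)
  k <- gauss_kernel(sigma)
  a <- apply(v, c(2, 3), conv1d_reflect, k = k)
  a <- aperm(apply(a, c(1, 3), conv1d_reflect, k = k), c(2, 1, 3))
  aperm(apply(a, c(1, 2), conv1d_reflect, k = k), c(2, 3, 1))
}

# Felzenszwalb & Huttenlocher exact 1D squared distance transform.
edt1d_sq <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  INF <- 1e18
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -INF; z[2L] <- INF
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (s <= z[k] && k > 1L) {
        k <- k - 1L
      } else if (s <= z[k]) {
        v[1L] <- q; z[1L] <- -INF; z[2L] <- INF
        break
      } else {
        k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- INF
        break
      }
    }
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Squared Euclidean distance of every foreground pixel to the nearest
# background pixel centre (background pixels get 0).
edt2d_sq <- function(m) {
  f <- ifelse(m > 0, 1e18, 0)
  f <- apply(f, 2, edt1d_sq)
  t(apply(f, 1, edt1d_sq))
}

edt3d_sq <- function(v) {
  f <- ifelse(v > 0, 1e18, 0)
  f <- apply(f, c(2, 3), edt1d_sq)
  f <- aperm(apply(f, c(1, 3), edt1d_sq), c(2, 1, 3))
  aperm(apply(f, c(1, 2), edt1d_sq), c(2, 3, 1))
}

#' Boundary length of a binary region by marching squares
#'
#' Measures the total length of the 0.5 iso-contour of a binary 2D mask.
#' The mask is first smoothed with a small Gaussian (reflected boundaries) and
#' the contour is extracted with linear interpolation, which removes most of
#' the staircase bias of a purely binary marching-squares pass. Structures
#' that extend to the image edge are left open there (no closing segment is
#' added), so a plate spanning the full field contributes only its two long
#' sides.
#'
#' @param mask 2D binary matrix (any non-zero value is foreground).
#' @param smooth_sigma Gaussian pre-smoothing in pixels; 0 disables smoothing
#'   and reduces to binary midpoint marching squares.
#' @return Contour length in pixel units.
#' @export
perimeter_2d <- function(mask, smooth_sigma = 1.0) {
  mask <- (mask > 0) * 1
  if (sum(mask) == 0) return(0)
  f <- smooth2d(mask, smooth_sigma)
  ms_contour_length(f, iso = 0.5)
}

ms_contour_length <- function(f, iso = 0.5) {
  nr <- nrow(f); nc <- ncol(f)
  if (nr < 2L || nc < 2L) return(0)
  a <- f[-nr, -nc]; b <- f[-nr, -1]; cc <- f[-1, -1]; d <- f[-1, -nc]
  A <- a >= iso; B <- b >= iso; C <- cc >= iso; D <- d >= iso
  sdiv <- function(num, den) ifelse(den == 0, 0.5, num / den)
  # cell corners: a=(0,0) b=(0,1) c=(1,1) d=(1,0) in (row, col)
  Tc <- sdiv(iso - a, b - a)           # top edge crossing  (0, Tc)
  Rr <- sdiv(iso - b, cc - b)          # right edge         (Rr, 1)
  Bc <- 1 - sdiv(iso - cc, d - cc)     # bottom edge        (1, Bc)
  Lr <- 1 - sdiv(iso - d, a - d)       # left edge          (Lr, 0)
  z <- a * 0; one <- z + 1
  seg <- function(w, p1r, p1c, p2r, p2c)
    sum(sqrt((p1r[w] - p2r[w])^2 + (p1c[w] - p2c[w])^2))
  idx <- A + 2 * B + 4 * C + 8 * D
  tot <- 0
  tot <- tot + seg(idx %in% c(1, 14), z, Tc, Lr, z)
  tot <- tot + seg(idx %in% c(2, 13), z, Tc, Rr, one)
  tot <- tot + seg(idx %in% c(4, 11), Rr, one, one, Bc)
  tot <- tot + seg(idx %in% c(8, 7), one, Bc, Lr, z)
  tot <- tot + seg(idx %in% c(3, 12), Lr, z, Rr, one)
  tot <- tot + seg(idx %in% c(6, 9), z, Tc, one, Bc)
  w <- idx %in% c(5, 10)
  tot <- tot + seg(w, z, Tc, Lr, z) + seg(w, Rr, one, one, Bc)
  tot
}

#' Iso-surface area of a binary volume
#'
#' Estimates the area of the 0.5 iso-surface of a binary 3D volume. The
#' indicator is smoothed with a small Gaussian (reflected boundaries) and the
#' surface is triangulated by marching tetrahedra (each voxel cell split into
#' six tetrahedra, vertices placed by linear interpolation). Foreground that
#' reaches the volume boundary is left open there, which is the convention
#' wanted for structures clipped by a VOI: clipped cross-sections do not count
#' as bone surface.
#'
#' @param vol 3D binary array.
#' @param smooth_sigma Gaussian pre-smoothing in voxels.
#' @return Surface area in voxel-squared units.
#' @export
surface_area_3d <- function(vol, smooth_sigma = 1.0) {
  vol <- (vol > 0) * 1
  if (sum(vol) == 0) return(0)
  f <- smooth3d(vol, smooth_sigma)
  mt_surface_area(f, iso = 0.5)
}

mt_surface_area <- function(f, iso = 0.5) {
  d <- dim(f)
  if (any(d < 2L)) return(0)
  n1 <- d[1] - 1L; n2 <- d[2] - 1L; n3 <- d[3] - 1L
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  idx <- as.matrix(expand.grid(i = 1:n1, j = 1:n2, k = 1:n3))
  V <- matrix(0, nrow(idx), 8)
  for (c8 in 1:8)
    V[, c8] <- f[cbind(idx[, 1] + corner[c8, 1], idx[, 2] + corner[c8, 2],
                       idx[, 3] + corner[c8, 3])]
  mixed <- (rowSums(V >= iso) > 0) & (rowSums(V < iso) > 0)
  if (!any(mixed)) return(0)
  V <- V[mixed, , drop = FALSE]
  tri_area <- function(p1, p2, p3) {
    u <- p2 - p1; w <- p3 - p1
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  lerp <- function(pa, pb, va, vb) pa + ((iso - va) / (vb - va)) * (pb - pa)
  total <- 0
  for (t in 1:6) {
    cid <- tets[t, ]
    v <- V[, cid, drop = FALSE]
    P <- lapply(1:4, function(m)
      matrix(corner[cid[m], ], nrow(v), 3, byrow = TRUE))
    inside <- v >= iso
    k <- rowSums(inside)
    for (solo in 1:4) {
      w <- (k == 1 & inside[, solo]) | (k == 3 & !inside[, solo])
      if (!any(w)) next
      oth <- setdiff(1:4, solo)
      p1 <- lerp(P[[solo]][w, , drop = FALSE], P[[oth[1]]][w, , drop = FALSE],
                 v[w, solo], v[w, oth[1]])
      p2 <- lerp(P[[solo]][w, , drop = FALSE], P[[oth[2]]][w, , drop = FALSE],
                 v[w, solo], v[w, oth[2]])
      p3 <- lerp(P[[solo]][w, , drop = FALSE], P[[oth[3]]][w, , drop = FALSE],
                 v[w, solo], v[w, oth[3]])
      total <- total + sum(tri_area(p1, p2, p3))
    }
    for (pr in list(c(1, 2), c(1, 3), c(1, 4))) {
      o <- setdiff(1:4, pr)
      w <- k == 2 & ((inside[, pr[1]] & inside[, pr[2]]) |
                       (inside[, o[1]] & inside[, o[2]]))
      if (!any(w)) next
      q1 <- lerp(P[[pr[1]]][w, , drop = FALSE], P[[o[1]]][w, , drop = FALSE],
                 v[w, pr[1]], v[w, o[1]])
      q2 <- lerp(P[[pr[1]]][w, , drop = FALSE], P[[o[2]]][w, , drop = FALSE],
                 v[w, pr[1]], v[w, o[2]])
      q3 <- lerp(P[[pr[2]]][w, , drop = FALSE], P[[o[2]]][w, , drop = FALSE],
                 v[w, pr[2]], v[w, o[2]])
      q4 <- lerp(P[[pr[2]]][w, , drop = FALSE], P[[o[1]]][w, , drop = FALSE],
                 v[w, pr[2]], v[w, o[1]])
      total <- total + sum(tri_area(q1, q2, q3)) + sum(tri_area(q1, q3, q4))
    }
  }
  total
}

# Sphere/disc painting local thickness (Hildebrand & Ruegsegger style):
# every foreground element gets the diameter of the largest inscribed
# disc/sphere that covers it. Returns the thickness map in pixel units.
local_thickness_map <- function(mask, ndim = length(dim(mask))) {
  d <- dim(mask)
  fg <- mask > 0
  if (!any(fg)) return(array(0, d))
  r <- if (ndim == 2L) sqrt(edt2d_sq(fg * 1)) else sqrt(edt3d_sq(fg * 1))
  rv <- r[fg]
  centers <- which(fg, arr.ind = TRUE)
  thv <- numeric(prod(d))
  lin <- function(ix) {
    if (ndim == 2L) ix[, 1] + (ix[, 2] - 1) * d[1]
    else ix[, 1] + (ix[, 2] - 1) * d[1] + (ix[, 3] - 1) * d[1] * d[2]
  }
  for (radius in sort(unique(rv), decreasing = TRUE)) {
    sel <- rv == radius
    ctr <- centers[sel, , drop = FALSE]
    # skip centres already covered by a strictly larger sphere
    covered <- thv[lin(ctr)] >= 2 * radius
    ctr <- ctr[!covered, , drop = FALSE]
    if (nrow(ctr) == 0L) next
    R <- floor(radius)
    og <- if (ndim == 2L) expand.grid(di = -R:R, dj = -R:R)
          else expand.grid(di = -R:R, dj = -R:R, dk = -R:R)
    og <- og[rowSums(og^2) <= radius^2, , drop = FALSE]
    for (o in seq_len(nrow(og))) {
      q <- sweep(ctr, 2, as.numeric(og[o, ]), "+")
      ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2]
      if (ndim == 3L) ok <- ok & q[, 3] >= 1 & q[, 3] <= d[3]
      li <- lin(q[ok, , drop = FALSE])
      thv[li] <- pmax(thv[li], 2 * radius)
    }
  }
  th <- array(thv, d)
  th[!fg] <- 0
  th
}

#' Mean local thickness of a binary structure
#'
#' Volume-weighted mean of the maximal-inscribed-disc (2D) or
#' maximal-inscribed-sphere (3D) diameter over all foreground elements,
#' the direct (model-independent) thickness used in bone morphometry.
#'
#' @param mask 2D or 3D binary array.
#' @return Mean thickness in pixel units (0 for an empty mask).
#' @export
local_thickness_mean <- function(mask) {
  fg <- mask > 0
  if (!any(fg)) return(0)
  th <- local_thickness_map(mask)
  mean(th[fg])
}

#' Euler characteristic of a voxel complex
#'
#' Computes the Euler characteristic of the cubical complex spanned by the
#' foreground voxels (vertices - edges + faces - cubes of the union of closed
#' unit cubes). Voxels sharing a face, edge or corner are part of one
#' connected body, i.e. the 26-connectivity interpretation of foreground.
#'
#' @param vol 3D binary array.
#' @return Integer Euler characteristic.
#' @export
euler_characteristic_3d <- function(vol) {
  d <- dim(vol)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- vol > 0
  dp <- dim(p)
  count_cells <- function(shifts) {
    acc <- array(FALSE, dp + 1L)
    for (s in shifts) {
      a <- array(FALSE, dp + 1L)
      a[(1 + s[1]):(dp[1] + s[1]), (1 + s[2]):(dp[2] + s[2]),
        (1 + s[3]):(dp[3] + s[3])] <- p
      acc <- acc | a
    }
    sum(acc)
  }
  grid_shifts <- function(axes) {
    g <- expand.grid(lapply(axes, function(a) if (a) 0:1 else 0))
    lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
  }
  nC <- sum(p)
  nV <- count_cells(grid_shifts(c(TRUE, TRUE, TRUE)))
  nE <- count_cells(grid_shifts(c(FALSE, TRUE, TRUE))) +
    count_cells(grid_shifts(c(TRUE, FALSE, TRUE))) +
    count_cells(grid_shifts(c(TRUE, TRUE, FALSE)))
  nF <- count_cells(grid_shifts(c(TRUE, FALSE, FALSE))) +
    count_cells(grid_shifts(c(FALSE, TRUE, FALSE))) +
    count_cells(grid_shifts(c(FALSE, FALSE, TRUE)))
  as.integer(nV - nE + nF - nC)
}

# 3D binary dilation with a full 3x3x3 structuring element, one iteration.
dilate3d_26 <- function(vol) {
  d <- dim(vol)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- vol > 0
  acc <- array(FALSE, d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1)
    acc <- acc | p[(2 + di):(d[1] + 1L + di), (2 + dj):(d[2] + 1L + dj),
                   (2 + dk):(d[3] + 1L + dk)]
  acc * 1
}

# Connected component labelling of a 3D binary array (26- or 6-connectivity),
# flood fill over a frontier; used by tests as a Betti-number oracle and by
# the segmentation QC.
label_components_3d <- function(vol, connectivity = 26) {
  d <- dim(vol)
  fg <- which(vol > 0)
  lab <- integer(prod(d))
  if (length(fg) == 0L) return(array(lab, d))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  loff <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  # guard against wrap-around across rows/planes by checking coordinates
  coords <- arrayInd(fg, d)
  inside <- array(FALSE, d); inside[fg] <- TRUE
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    lab[s] <- cur
    while (length(frontier) > 0L) {
      ci <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        q <- sweep(ci, 2, offs[o, ], "+")
        ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
          q[, 3] >= 1 & q[, 3] <= d[3]
        if (!any(ok)) next
        li <- q[ok, 1] + (q[ok, 2] - 1) * d[1] + (q[ok, 3] - 1) * d[1] * d[2]
        li <- li[inside[li] & lab[li] == 0L]
        if (length(li) > 0L) {
          lab[li] <- cur
          nxt <- c(nxt, li)
        }
      }
      frontier <- unique(nxt)
    }
  }
  array(lab, d)
}
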