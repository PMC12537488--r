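#' @title Phase-XMCD projection forward model
#' @description Internal machinery: tilt-series projections are computed by
#'   resampling the volume on a grid rotated about the tilt axis (bilinear in
#'   the rotation plane, exact along the axis) and summing along the beam
#'   (`x`).  The back-projection is the exact adjoint (same weights,
#'   scatter instead of gather), which the reconstruction relies on.
#' @name forward_model
NULL

# Geometry cache for a tilt about y: the rotation only mixes (x, z), so the
# resampling is bilinear in the (x, z) plane and shared across y.  Returns,
# for each of the 4 bilinear corners, a row index into the (x, z)-flattened
# volume and a weight (0 outside the grid).
.tilt_geometry <- function(nx, nz, angle_deg) {
  a <- angle_deg * pi / 180
  cx <- (nx + 1) / 2
  cz <- (nz + 1) / 2
  lx <- matrix(seq_len(nx) - cx, nx, nz)
  lz <- matrix(seq_len(nz) - cz, nx, nz, byrow = TRUE)
  sx <- cos(a) * lx - sin(a) * lz + cx
  sz <- sin(a) * lx + cos(a) * lz + cz
  ix0 <- floor(sx); fx <- sx - ix0
  iz0 <- floor(sz); fz <- sz - iz0
  corners <- vector("list", 4L)
  n <- 1L
  for (dz in 0:1) for (dx in 0:1) {
    ix <- ix0 + dx; iz <- iz0 + dz
    w <- (if (dx == 0) 1 - fx else fx) * (if (dz == 0) 1 - fz else fz)
    ok <- ix >= 1 & ix <= nx & iz >= 1 & iz <= nz
    w[!ok] <- 0
    ix[!ok] <- 1L; iz[!ok] <- 1L
    corners[[n]] <- list(idx = as.vector(ix + nx * (iz - 1L)), w = as.vector(w))
    n <- n + 1L
  }
  corners
}

# volume [nx, ny, nz] -> (x,z)-flattened matrix [(nx*nz), ny]
.vol_to_xz <- function(V) {
  d <- dim(V)
  dim2 <- c(d[1] * d[3], d[2])
  m <- aperm(V, c(1, 3, 2))
  dim(m) <- dim2
  m
}

.xz_to_vol <- function(M, d) {
  dim(M) <- c(d[1], d[3], d[2])
  aperm(M, c(1, 3, 2))
}

# Projection of a scalar volume at one tilt angle about y.
# Returns an image [ny, nz] (tilt-axis coordinate first), in voxel units
# (multiply by voxel size for a physical line integral).
.project_scalar_tilt <- function(V, geom) {
  d <- dim(V)
  VM <- .vol_to_xz(V)
  W <- geom[[1]]$w * VM[geom[[1]]$idx, , drop = FALSE]
  for (n in 2:4) W <- W + geom[[n]]$w * VM[geom[[n]]$idx, , drop = FALSE]
  dim(W) <- c(d[1], d[3], d[2])
  t(colSums(W))                       # [nz, ny] -> [ny, nz]
}

# Exact adjoint of .project_scalar_tilt.
.backproject_scalar_tilt <- function(I, geom, d) {
  tI <- t(I)                          # [nz, ny]
  W <- tI[rep(seq_len(d[3]), each = d[1]), , drop = FALSE]  # [(nx*nz), ny]
  acc <- matrix(0, d[1] * d[3], d[2])
  for (n in 1:4) {
    r <- rowsum(geom[[n]]$w * W, geom[[n]]$idx)
    rows <- as.integer(rownames(r))
    acc[rows, ] <- acc[rows, ] + r
  }
  .xz_to_vol(acc, d)
}

# In-plane 90-degree pre-rotation of the sample about the beam axis (x),
# used for the second tilt series, and its inverse.  Both are exact index
# permutations; dimensions change [nx,ny,nz] -> [nx,nz,ny].
.rot90_vol <- function(V) {
  A <- aperm(V, c(1, 3, 2))
  A[, , rev(seq_len(dim(A)[3])), drop = FALSE]
}

.rot90_vol_inv <- function(W) {
  A <- aperm(W, c(1, 3, 2))
  A[, rev(seq_len(dim(A)[2])), , drop = FALSE]
}

# Beam direction (sample frame) for a tilt angle on a given rotation axis.
.beam_direction <- function(angle_deg, axis_id) {
  a <- angle_deg * pi / 180
  if (axis_id == "first") c(cos(a), 0, sin(a)) else c(cos(a), sin(a), 0)
}

#' Phase-XMCD projection of a vector field
#'
#' Each pixel is the line integral along the beam of the magnetization
#' component parallel to the beam direction, `integral M . b ds`, scaled by
#' a declared constant (default 1, arbitrary phase units).  The projection
#' is computed by resampling the volume on a beam-aligned grid (trilinear)
#' and summing along the beam; it is linear in the field and antisymmetric
#' under beam reversal.
#'
#' The image plane axes are: vertical = the projection of `y` (or a fallback
#' when the beam is near `y`), horizontal = `beam x vertical`.  For a beam
#' `(cos a, 0, sin a)` this matches the first-axis tilt-series convention
#' exactly.
#'
#' @param field a [vector_field3d] (must carry a mask).
#' @param beam_direction unit length-3 vector in the sample frame.
#' @param scale signal scale constant.
#' @return A matrix (image) in signal units; pixel size equals the voxel
#'   size.
#' @export
xmcd_project <- function(field, beam_direction, scale = 1) {
  if (is.null(field$mask)) stop_invalid("field must carry a mask")
  b <- beam_direction / sqrt(sum(beam_direction^2))
  maps <- .project_general(list(field$mx, field$my, field$mz), b)
  (maps[[1]] * b[1] + maps[[2]] * b[2] + maps[[3]] * b[3]) *
    scale * field$voxel_size
}

#' Projected-thickness (charge) map of a mask
#'
#' Line integral of the indicator function of the particle along the beam:
#' the non-magnetic phase image used as the alignment reference.
#'
#' @param mask logical voxel array with a `voxel_size` attribute (or a
#'   [vector_field3d], whose mask is used).
#' @param beam_direction unit beam vector.
#' @return Thickness map (m).
#' @export
charge_project <- function(mask, beam_direction = c(1, 0, 0)) {
  if (inherits(mask, "vector_field3d")) {
    h <- mask$voxel_size
    m <- mask$mask
  } else {
    h <- attr(mask, "voxel_size")
    m <- mask
  }
  if (is.null(h)) stop_invalid("mask must carry a voxel_size attribute")
  b <- beam_direction / sqrt(sum(beam_direction^2))
  .project_general(list(array(as.numeric(m), dim(m))), b)[[1]] * h
}

# General projection of scalar volumes along an arbitrary beam direction by
# trilinear resampling on a beam-aligned grid.  Shares weights across the
# supplied volumes.
.project_general <- function(vols, b) {
  d <- dim(vols[[1]])
  # image frame: u1 = beam, v = in-plane vertical (projection of y), w = u1 x v
  v <- c(0, 1, 0) - b[2] * b
  if (sqrt(sum(v^2)) < 1e-8) v <- c(0, 0, 1) - b[3] * b
  v <- v / sqrt(sum(v^2))
  w <- c(b[2] * v[3] - b[3] * v[2], b[3] * v[1] - b[1] * v[3],
         b[1] * v[2] - b[2] * v[1])
  cx <- (d + 1) / 2
  lx <- (seq_len(d[1]) - cx[1])
  ly <- (seq_len(d[2]) - cx[2])
  lz <- (seq_len(d[3]) - cx[3])
  # sample coordinate s = lx*b + ly*v + lz*w (+ center)
  n <- prod(d)
  LX <- array(lx, d)
  LY <- array(rep(ly, each = d[1]), d)
  LZ <- array(rep(lz, each = d[1] * d[2]), d)
  maps <- vector("list", length(vols))
  for (m in seq_along(maps)) maps[[m]] <- matrix(0, d[2], d[3])
  sx <- LX * b[1] + LY * v[1] + LZ * w[1] + cx[1]
  sy <- LX * b[2] + LY * v[2] + LZ * w[2] + cx[2]
  sz <- LX * b[3] + LY * v[3] + LZ * w[3] + cx[3]
  ix0 <- floor(sx); fx <- sx - ix0
  iy0 <- floor(sy); fy <- sy - iy0
  iz0 <- floor(sz); fz <- sz - iz0
  acc <- vector("list", length(vols))
  for (m in seq_along(vols)) acc[[m]] <- array(0, d)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ix <- ix0 + dx; iy <- iy0 + dy; iz <- iz0 + dz
    wt <- (if (dx == 0) 1 - fx else fx) *
          (if (dy == 0) 1 - fy else fy) *
          (if (dz == 0) 1 - fz else fz)
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    wt[!ok] <- 0
    ix[!ok] <- 1L; iy[!ok] <- 1L; iz[!ok] <- 1L
    li <- ix + d[1] * (iy - 1L) + d[1] * d[2] * (iz - 1L)
    for (m in seq_along(vols))
      acc[[m]] <- acc[[m]] + wt * array(vols[[m]][li], d)
  }
  lapply(acc, function(a) colSums(a))    # sum along beam axis -> [ny, nz]
}

# Bilinear subpixel shift of an image (zero boundary).  Positive shift moves
# features toward larger indices.
.shift_image <- function(I, s1, s2) {
  d <- dim(I)
  i1 <- matrix(seq_len(d[1]) - s1, d[1], d[2])
  i2 <- matrix(seq_len(d[2]) - s2, d[1], d[2], byrow = TRUE)
  a0 <- floor(i1); f1 <- i1 - a0
  b0 <- floor(i2); f2 <- i2 - b0
  out <- matrix(0, d[1], d[2])
  for (db in 0:1) for (da in 0:1) {
    aa <- a0 + da; bb <- b0 + db
    w <- (if (da == 0) 1 - f1 else f1) * (if (db == 0) 1 - f2 else f2)
    ok <- aa >= 1 & aa <= d[1] & bb >= 1 & bb <= d[2]
    w[!ok] <- 0; aa[!ok] <- 1L; bb[!ok] <- 1L
    out <- out + w * matrix(I[cbind(as.vector(aa), as.vector(bb))], d[1], d[2])
  }
  out
}

#' Construct a tilt series object
#'
#' @param images list of image matrices (uniform dimensions), one per angle.
#' @param angles tilt angles in degrees, strictly increasing.
#' @param axis_id `"first"` (tilt about `y`) or `"second"` (sample
#'   pre-rotated 90 degrees about the beam axis, then tilted about `y`).
#' @param pixel_size pixel size (m).
#' @param applied_shifts optional n x 2 matrix of true per-image shifts
#'   (pixels, image row/column directions).
#' @param charge_images optional list of non-magnetic thickness maps.
#' @param volume_dim dimensions of the originating volume grid, if known.
#' @return An object of class `tilt_series`.
#' @export
tilt_series <- function(images, angles, axis_id = c("first", "second"),
                        pixel_size, applied_shifts = NULL,
                        charge_images = NULL, volume_dim = NULL) {
  axis_id <- match.arg(axis_id)
  if (length(images) != length(angles))
    stop_invalid("need one angle per image")
  if (any(diff(angles) <= 0))
    stop_invalid("angles must be strictly increasing")
  if (pixel_size <= 0) stop_invalid("pixel_size must be positive")
  d <- dim(images[[1]])
  if (!all(vapply(images, function(i) identical(dim(i), d), logical(1))))
    stop_invalid("image dimensions must be uniform across the stack")
  if (is.null(applied_shifts))
    applied_shifts <- matrix(0, length(images), 2)
  structure(list(images = images, angles = as.numeric(angles),
                 axis_id = axis_id, pixel_size = pixel_size,
                 applied_shifts = applied_shifts,
                 charge_images = charge_images,
                 volume_dim = volume_dim),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("tilt_series (%s axis): %d images %d x %d, angles %g..%g deg\n",
              x$axis_id, length(x$images), d[1], d[2],
              min(x$angles), max(x$angles)))
  invisible(x)
}

#' Simulate a phase-XMCD tilt series
#'
#' Projects the field at every requested tilt angle about the chosen
#' rotation axis.  For the first axis the sample is tilted about `y`; for
#' the second it is first rotated 90 degrees about the sample normal (the
#' beam axis at zero tilt) and then tilted.  Gaussian signal noise and
#' random rigid shifts (integer plus subpixel) are applied per image, with
#' the true shifts recorded, and matching non-magnetic thickness maps are
#' generated as the alignment reference.
#'
#' @param field a [vector_field3d].
#' @param axis_id `"first"` or `"second"`.
#' @param angles tilt angles (degrees), strictly increasing, within
#'   (-90, 90).
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param shift_sd standard deviation of the random per-image shifts
#'   (pixels); shifts combine an integer and a subpixel part.
#' @param seed integer seed; the simulation is deterministic given the seed.
#' @param scale XMCD signal scale constant.
#' @return A [tilt_series]; pixel size equals the voxel size.
#' @export
simulate_tilt_series <- function(field, axis_id = c("first", "second"),
                                 angles, noise_sd = 0, shift_sd = 0,
                                 seed = 1, scale = 1) {
  axis_id <- match.arg(axis_id)
  if (any(angles <= -90 | angles >= 90))
    stop_invalid("angles must lie within (-90, 90) degrees")
  vols <- list(field$mx, field$my, field$mz)
  maskv <- array(as.numeric(field$mask), dim(field$mask))
  if (axis_id == "second") {
    vols <- lapply(vols, .rot90_vol)
    maskv <- .rot90_vol(maskv)
  }
  d <- dim(vols[[1]])
  h <- field$voxel_size
  n <- length(angles)
  images <- vector("list", n)
  charges <- vector("list", n)
  shifts <- matrix(0, n, 2)
  with_seed(seed, {
    for (i in seq_len(n)) {
      geom <- .tilt_geometry(d[1], d[3], angles[i])
      b <- .beam_direction(angles[i], axis_id)
      img <- scale * h * (
        b[1] * .project_scalar_tilt(vols[[1]], geom) +
        b[2] * .project_scalar_tilt(vols[[2]], geom) +
        b[3] * .project_scalar_tilt(vols[[3]], geom))
      chg <- h * .project_scalar_tilt(maskv, geom)
      if (shift_sd > 0) {
        s <- round(stats::rnorm(2, 0, shift_sd)) + stats::rnorm(2, 0, 0.3)
        img <- .shift_image(img, s[1], s[2])
        chg <- .shift_image(chg, s[1], s[2])
        shifts[i, ] <- s
      }
      if (noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                            nrow(img), ncol(img))
      images[[i]] <- img
      charges[[i]] <- chg
    }
  })
  tilt_series(images, angles, axis_id, pixel_size = h,
              applied_shifts = shifts, charge_images = charges,
              volume_dim = dim(field$mx))
}
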