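#' Stacked-frustrum particle geometry
#'
#' A `particle_geometry` describes an axially symmetric (optionally
#' elliptical) solid as a stack of truncated-cone slabs along the long axis
#' `z`.  The radial profile is stored as the major radius at every slab
#' boundary; the cross-section at height `z` is an ellipse with major radius
#' `a(z)` (along `x`) and minor radius `ellipticity * a(z)` (along `y`).
#'
#' @param frustrum_heights numeric vector of slab heights (m).
#' @param major_radii numeric vector of major radii (m) at the
#'   `length(frustrum_heights) + 1` slab boundaries, base first.
#' @param ellipticity ratio of minor to major radius, in (0, 1].
#'
#' @return An object of class `particle_geometry` with fields
#'   `frustrum_heights`, `major_radii`, `ellipticity`, `long_axis_length`
#'   and `boundaries` (cumulative slab boundary positions, m).
#' @export
particle_geometry <- function(frustrum_heights, major_radii, ellipticity = 1) {
  frustrum_heights <- as.numeric(frustrum_heights)
  major_radii <- as.numeric(major_radii)
  if (length(frustrum_heights) == 0)
    stop_invalid("geometry must contain at least one frustrum (zero length)")
  if (length(major_radii) != length(frustrum_heights) + 1L)
    stop_invalid("need one major radius per slab boundary (%d slabs -> %d radii)",
                 length(frustrum_heights), length(frustrum_heights) + 1L)
  if (any(frustrum_heights <= 0)) stop_invalid("all frustrum heights must be positive")
  if (any(major_radii <= 0)) stop_invalid("all radii must be positive")
  if (ellipticity <= 0 || ellipticity > 1)
    stop_invalid("ellipticity must lie in (0, 1]")
  d <- diff(major_radii)
  # profile must be single-peaked or monotone from base to tip
  s <- sign(d[d != 0])
  if (length(s) && any(diff(s) > 0))
    stop_invalid("radial profile must be monotone or single-peaked from base to tip")
  L <- sum(frustrum_heights)
  structure(list(
    frustrum_heights = frustrum_heights,
    major_radii = major_radii,
    ellipticity = ellipticity,
    long_axis_length = L,
    boundaries = c(0, cumsum(frustrum_heights))
  ), class = "particle_geometry")
}

#' @export
print.particle_geometry <- function(x, ...) {
  cat(sprintf(
    "particle_geometry: %d frustrums, length %.3g um, base major radius %.3g um, tip %.3g um, ellipticity %.2f\n",
    length(x$frustrum_heights), x$long_axis_length * 1e6,
    x$major_radii[1] * 1e6, x$major_radii[length(x$major_radii)] * 1e6,
    x$ellipticity))
  invisible(x)
}

#' Idealized spearhead geometry
#'
#' Builds the idealized spearhead used throughout the package: a cylindrical
#' body over the first `body_fraction` of the length, then a linear taper to
#' the tip radius, smoothed over `smooth_slabs` slabs at the junction, and
#' discretized into `n_frustrums` slabs of equal height.  The defaults
#' reproduce the giant spearhead magnetofossil dimensions (base radius
#' 0.55 um, tip radius 0.058 um, length 2.25 um, 90 frustrums of 25 nm,
#' minor/major axis ratio 0.85).
#'
#' @param base_radius,tip_radius,total_length dimensions (m);
#'   `tip_radius < base_radius`, all positive.
#' @param n_frustrums number of slabs (>= 2).
#' @param ellipticity minor/major cross-section ratio in (0, 1].
#' @param body_fraction fraction of the length occupied by the cylindrical
#'   body before the taper begins.
#' @param smooth_slabs half-width (in slabs) of the moving-average smoothing
#'   applied at the body/tip junction.
#'
#' @return A [particle_geometry].
#' @examples
#' geo <- build_spearhead_geometry()
#' range(geo$frustrum_heights)  # 90 slabs of 25 nm
#' @export
build_spearhead_geometry <- function(base_radius = 0.55e-6,
                                     tip_radius = 0.058e-6,
                                     total_length = 2.25e-6,
                                     n_frustrums = 90,
                                     ellipticity = 0.85,
                                     body_fraction = 0.55,
                                     smooth_slabs = 2) {
  if (base_radius <= 0 || tip_radius <= 0 || total_length <= 0)
    stop_invalid("all dimensions must be positive")
  if (tip_radius >= base_radius)
    stop_invalid("tip_radius must be smaller than base_radius")
  if (n_frustrums < 2) stop_invalid("n_frustrums must be at least 2")
  h <- rep(total_length / n_frustrums, n_frustrums)
  zb <- seq(0, total_length, length.out = n_frustrums + 1L)
  zbreak <- body_fraction * total_length
  r <- ifelse(zb <= zbreak, base_radius,
              base_radius + (tip_radius - base_radius) *
                (zb - zbreak) / (total_length - zbreak))
  if (smooth_slabs > 0 && n_frustrums > 2 * smooth_slabs) {
    w <- 2L * as.integer(smooth_slabs) + 1L
    rs <- stats::filter(r, rep(1 / w, w), sides = 2)
    keep <- !is.na(rs)
    r[keep] <- rs[keep]
    r[1] <- base_radius
    r[length(r)] <- tip_radius
  }
  particle_geometry(h, r, ellipticity)
}

#' Major radius of a geometry at height z
#'
#' Linear interpolation of the slab-boundary radial profile; zero outside
#' `[0, long_axis_length]`.
#'
#' @param geometry a [particle_geometry].
#' @param z heights (m) along the long axis, measured from the base.
#' @return Major radii (m) at `z`.
#' @export
radius_at <- function(geometry, z) {
  r <- stats::approx(geometry$boundaries, geometry$major_radii, xout = z,
                     yleft = 0, yright = 0, rule = 1)$y
  r[is.na(r)] <- 0
  r
}

#' Voxelize a particle geometry
#'
#' Samples the frustrum solid on a regular cubic voxel grid.  A voxel is
#' inside when its center lies inside the solid.  The grid is centered on the
#' long axis with one voxel of padding on every side; voxel centers sit at
#' `origin + (index - 0.5) * voxel_size` (1-based indices).
#'
#' @param geometry a [particle_geometry].
#' @param voxel_size cubic voxel edge length (m); must not exceed a quarter
#'   of the base minor radius.
#' @param pad number of empty voxels added on each side of the bounding box.
#' @return A logical 3D array with attributes `voxel_size` and `origin`
#'   (physical position of the grid corner, m).  The long axis is the third
#'   array dimension (`z`).
#' @export
voxelize <- function(geometry, voxel_size, pad = 1L) {
  if (voxel_size <= 0) stop_invalid("voxel_size must be positive")
  rmax <- max(geometry$major_radii)
  rmin_base <- geometry$ellipticity * max(geometry$major_radii)
  if (voxel_size > rmin_base / 4)
    stop_invalid(paste0(
      "voxel_size %.3g m is too coarse: it must be at most a quarter of the ",
      "base minor radius (%.3g m) to resolve the cross-section"),
      voxel_size, rmin_base)
  h <- voxel_size
  nx <- 2L * (as.integer(ceiling(rmax / h)) + pad)
  ny <- 2L * (as.integer(ceiling(geometry$ellipticity * rmax / h)) + pad)
  nz <- as.integer(ceiling(geometry$long_axis_length / h)) + 2L * pad
  origin <- c(-nx / 2 * h, -ny / 2 * h, -pad * h)
  xs <- origin[1] + (seq_len(nx) - 0.5) * h
  ys <- origin[2] + (seq_len(ny) - 0.5) * h
  zs <- origin[3] + (seq_len(nz) - 0.5) * h
  a <- radius_at(geometry, zs)                      # major radius per slice
  mask <- array(FALSE, dim = c(nx, ny, nz))
  e <- geometry$ellipticity
  x2 <- matrix(xs^2, nx, ny)
  y2 <- matrix(ys^2, nx, ny, byrow = TRUE)
  for (k in seq_len(nz)) {
    if (a[k] <= 0) next
    mask[, , k] <- x2 / a[k]^2 + y2 / (e * a[k])^2 <= 1
  }
  attr(mask, "voxel_size") <- h
  attr(mask, "origin") <- origin
  mask
}

#' Voxel-center physical coordinates of a mask grid
#'
#' @param mask logical array from [voxelize()] (or any array with
#'   `voxel_size`/`origin` attributes).
#' @return A list with numeric vectors `x`, `y`, `z` of voxel-center
#'   coordinates (m) along each axis.
#' @export
grid_coordinates <- function(mask) {
  h <- attr(mask, "voxel_size")
  o <- attr(mask, "origin")
  d <- dim(mask)
  list(x = o[1] + (seq_len(d[1]) - 0.5) * h,
       y = o[2] + (seq_len(d[2]) - 0.5) * h,
       z = o[3] + (seq_len(d[3]) - 0.5) * h)
}
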