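#' Voxelized 3D magnetization vector field
#'
#' Container for a magnetization field sampled on a regular cubic voxel grid.
#' Components are stored as 3D arrays in A/m; the particle long axis is `z`
#' (third dimension), the beam direction at zero tilt is `x` (first
#' dimension), and the axes are right-handed.  Magnetization is identically
#' zero outside the mask.
#'
#' @param mx,my,mz numeric 3D arrays (A/m) of identical dimensions.
#' @param voxel_size voxel edge length (m).
#' @param mask logical array of the same dimensions; voxels outside are
#'   forced to zero magnetization.
#' @param origin physical position (m) of the grid corner; defaults to the
#'   `origin` attribute of `mask`, else the grid is centered at zero.
#'
#' @return An object of class `vector_field3d` with fields `mx`, `my`, `mz`,
#'   `mask`, `voxel_size`, `origin`.
#' @export
vector_field3d <- function(mx, my, mz, voxel_size, mask, origin = NULL) {
  d <- dim(mx)
  if (!identical(d, dim(my)) || !identical(d, dim(mz)) || !identical(d, dim(mask)))
    stop_invalid("component and mask dimensions must agree")
  if (voxel_size <= 0) stop_invalid("voxel_size must be positive")
  if (is.null(origin)) origin <- attr(mask, "origin")
  if (is.null(origin)) origin <- -d / 2 * voxel_size
  mask <- array(as.logical(mask), d)
  attr(mask, "voxel_size") <- voxel_size
  attr(mask, "origin") <- origin
  mx[!mask] <- 0; my[!mask] <- 0; mz[!mask] <- 0
  structure(list(mx = mx, my = my, mz = mz, mask = mask,
                 voxel_size = voxel_size, origin = origin),
            class = "vector_field3d")
}

#' @export
print.vector_field3d <- function(x, ...) {
  d <- dim(x$mx)
  rng <- if (any(x$mask)) range(field_magnitude(x)[x$mask]) else c(0, 0)
  cat(sprintf(
    "vector_field3d: %d x %d x %d voxels of %.3g nm, %d inside mask, |M| range %.3g..%.3g A/m\n",
    d[1], d[2], d[3], x$voxel_size * 1e9, sum(x$mask), rng[1], rng[2]))
  invisible(x)
}

#' Per-voxel magnetization magnitude
#' @param field a [vector_field3d].
#' @return Array of |M| (A/m).
#' @export
field_magnitude <- function(field) {
  sqrt(field$mx^2 + field$my^2 + field$mz^2)
}

#' Renormalize a field to a uniform magnitude inside the mask
#' @param field a [vector_field3d].
#' @param M_s target magnitude (A/m).
#' @return A [vector_field3d] with |M| = `M_s` inside the mask.
#' @export
normalize_field <- function(field, M_s = 1) {
  mag <- field_magnitude(field)
  sc <- array(0, dim(mag))
  ok <- field$mask & mag > 0
  sc[ok] <- M_s / mag[ok]
  vector_field3d(field$mx * sc, field$my * sc, field$mz * sc,
                 field$voxel_size, field$mask, field$origin)
}

#' Net magnetic moment of a field
#'
#' Integrates the magnetization over the grid: `m = sum(M) * voxel volume`.
#'
#' @param field a [vector_field3d].
#' @return Numeric length-3 moment vector (A m^2).
#' @export
net_moment <- function(field) {
  v <- field$voxel_size^3
  c(sum(field$mx), sum(field$my), sum(field$mz)) * v
}

#' Scale or combine vector fields linearly
#' @param a,b scalars.
#' @param f1,f2 [vector_field3d] objects on the same grid (mask is taken
#'   from `f1`; `f2` may be NULL for pure scaling).
#' @keywords internal
field_lincomb <- function(a, f1, b = 0, f2 = NULL) {
  if (is.null(f2))
    return(vector_field3d(a * f1$mx, a * f1$my, a * f1$mz,
                          f1$voxel_size, f1$mask, f1$origin))
  vector_field3d(a * f1$mx + b * f2$mx, a * f1$my + b * f2$my,
                 a * f1$mz + b * f2$mz, f1$voxel_size, f1$mask, f1$origin)
}
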