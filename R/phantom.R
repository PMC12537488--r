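#' Specification of an analytic single-vortex phantom
#'
#' Describes the topological features of a synthetic single-vortex
#' magnetization texture: the vortex core trajectory (control points
#' interpolated along `z`), an optional core-polarity reversal (Bloch point)
#' at a fractional position along the length, the circulation sense, an
#' optional reversal of the lateral M_z half-pattern in the tip (seen as a
#' twist of the medial domain wall), and the core radius.
#'
#' @param core_path_control_points numeric matrix with columns (x, y, z) in
#'   meters; at least two rows, strictly increasing in z.  The path is
#'   interpolated through these points as x(z), y(z).
#' @param polarity_flip_position fractional position in \[0, 1\] along the
#'   core at which the core polarization reverses sign, or `NA`/`NULL` for
#'   no reversal.  May be a vector for multiple reversals.
#' @param circulation_sense +1 or -1, the in-plane winding sense.
#' @param tip_mz_reversal logical; reverse the lateral M_z half-pattern over
#'   the tip region (twisting the medial wall).
#' @param core_radius 1/e radius (m) of the Gaussian core cant; default
#'   60 nm, comparable to the experimental resolution floor.
#' @param wall_amplitude amplitude (fraction of M_s) of the lateral M_z
#'   half-pattern away from the core.
#' @param tip_fraction fractional length over which the tip reversal's wall
#'   rotation takes place (counted back from the tip).
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(core_path_control_points,
                         polarity_flip_position = NULL,
                         circulation_sense = 1L,
                         tip_mz_reversal = FALSE,
                         core_radius = 60e-9,
                         wall_amplitude = 0.4,
                         tip_fraction = 0.25) {
  p <- as.matrix(core_path_control_points)
  if (ncol(p) != 3 || nrow(p) < 2)
    stop_invalid("core_path_control_points must be an n x 3 matrix, n >= 2")
  if (any(diff(p[, 3]) <= 0))
    stop_invalid("control points must be strictly increasing in z")
  if (!circulation_sense %in% c(-1, 1))
    stop_invalid("circulation_sense must be +1 or -1")
  if (core_radius <= 0) stop_invalid("core_radius must be positive")
  flips <- polarity_flip_position
  if (length(flips) == 0 || all(is.na(flips))) flips <- numeric(0)
  if (any(flips < 0 | flips > 1)) stop_invalid("flip positions must lie in [0, 1]")
  structure(list(core_path_control_points = p,
                 polarity_flip_position = sort(flips),
                 circulation_sense = as.integer(circulation_sense),
                 tip_mz_reversal = isTRUE(tip_mz_reversal),
                 core_radius = core_radius,
                 wall_amplitude = wall_amplitude,
                 tip_fraction = tip_fraction),
            class = "phantom_spec")
}

#' Interpolated core path of a phantom spec
#' @param spec a [phantom_spec].
#' @param z heights (m) at which to evaluate the path.
#' @return Matrix with columns (x, y) of the core position at each z
#'   (natural-spline interpolation, clamped to the control range).
#' @export
core_path_at <- function(spec, z) {
  p <- spec$core_path_control_points
  zc <- pmin(pmax(z, p[1, 3]), p[nrow(p), 3])
  if (nrow(p) == 2) {
    x <- stats::approx(p[, 3], p[, 1], xout = zc)$y
    y <- stats::approx(p[, 3], p[, 2], xout = zc)$y
  } else {
    x <- stats::spline(p[, 3], p[, 1], xout = zc, method = "natural")$y
    y <- stats::spline(p[, 3], p[, 2], xout = zc, method = "natural")$y
  }
  cbind(x = x, y = y)
}

#' Build an analytic single-vortex magnetization phantom
#'
#' Constructs a unit-|M| vortex texture inside the voxelized geometry:
#' in-plane circulation about the interpolated core path with the requested
#' sense; a Gaussian cant toward +/- z within the core radius, whose sign
#' (the core polarization) reverses at each `polarity_flip_position`; and a
#' weaker lateral M_z half-pattern, antisymmetric across the medial plane
#' through the core, giving the M_z = 0 medial domain wall.  With
#' `tip_mz_reversal` the wall normal rotates by 180 degrees over the tip
#' region so the half-pattern reverses (a medial-wall twist).  The result is
#' scaled to `|M| = M_s` everywhere inside the mask.
#'
#' @param geometry a [particle_geometry].
#' @param spec a [phantom_spec] whose core path stays inside the solid.
#' @param M_s saturation magnetization (A/m).
#' @param voxel_size voxel edge (m).
#' @param pad empty voxels around the particle (useful when simulating
#'   shifted projections).
#' @return A [vector_field3d].
#' @examples
#' geo <- build_spearhead_geometry(n_frustrums = 30)
#' sp <- phantom_spec(rbind(c(0, 0, 0), c(0, 0, 2.25e-6)),
#'                    polarity_flip_position = 0.5)
#' ph <- make_vortex_phantom(geo, sp, M_s = 4.80768e5, voxel_size = 50e-9)
#' @export
make_vortex_phantom <- function(geometry, spec, M_s, voxel_size, pad = 1L) {
  mask <- voxelize(geometry, voxel_size, pad = pad)
  g <- grid_coordinates(mask)
  d <- dim(mask)
  L <- geometry$long_axis_length
  # validate that the core path lies inside the solid
  pz <- spec$core_path_control_points[, 3]
  zchk <- seq(max(min(pz), 1e-4 * L), min(max(pz), L - 1e-4 * L), length.out = 64)
  cp <- core_path_at(spec, zchk)
  amaj <- radius_at(geometry, zchk)
  e <- geometry$ellipticity
  inside <- (cp[, 1] / pmax(amaj, 1e-300))^2 +
    (cp[, 2] / pmax(e * amaj, 1e-300))^2 < 1
  if (!all(inside[amaj > 0]))
    stop_invalid("core path exits the solid between its endpoints")

  core <- core_path_at(spec, g$z)          # nz x 2
  # core polarization sign per slice: starts +1, flips at given fractions
  frac <- g$z / L
  pol <- rep(1, d[3])
  for (f in spec$polarity_flip_position) pol <- pol * ifelse(frac >= f, -1, 1)
  # wall-normal angle per slice: 0 in the body; rotates to 180 deg over the tip
  gamma <- rep(0, d[3])
  if (spec$tip_mz_reversal) {
    z0 <- 1 - spec$tip_fraction
    t <- pmin(pmax((frac - z0) / (spec$tip_fraction * 0.8), 0), 1)
    gamma <- pi * t
  }

  s <- spec$circulation_sense
  rc <- spec$core_radius
  w <- spec$wall_amplitude
  wall_width <- 3 * voxel_size
  mx <- array(0, d); my <- array(0, d); mz <- array(0, d)
  X <- matrix(g$x, d[1], d[2])
  Y <- matrix(g$y, d[1], d[2], byrow = TRUE)
  for (k in seq_len(d[3])) {
    mk <- mask[, , k]
    if (!any(mk)) next
    rx <- X - core[k, 1]
    ry <- Y - core[k, 2]
    rho <- sqrt(rx^2 + ry^2)
    core_w <- exp(-(rho / rc)^2)
    # lateral half-pattern: antisymmetric across the (rotated) medial plane
    n_r <- ry * cos(gamma[k]) - rx * sin(gamma[k])
    mzk <- pol[k] * core_w +
      s * w * tanh(n_r / wall_width) * (1 - core_w)
    mzk <- pmin(pmax(mzk, -1), 1)
    ip <- sqrt(pmax(1 - mzk^2, 0))
    rho_safe <- pmax(rho, 1e-3 * voxel_size)
    mxk <- -s * ry / rho_safe * ip
    myk <- s * rx / rho_safe * ip
    mx[, , k] <- ifelse(mk, mxk, 0)
    my[, , k] <- ifelse(mk, myk, 0)
    mz[, , k] <- ifelse(mk, mzk, 0)
  }
  normalize_field(
    vector_field3d(M_s * mx, M_s * my, M_s * mz, voxel_size, mask), M_s)
}

#' Perturb a field with random angular noise
#'
#' Rotates each inside-mask vector by a random angle (Gaussian with the given
#' standard deviation) about a random axis perpendicular to the vector.  The
#' magnitude of every vector is preserved, and the result is deterministic
#' for a fixed seed.
#'
#' @param field a [vector_field3d].
#' @param angular_noise_sd standard deviation of the rotation angle (rad).
#' @param seed integer seed.
#' @return A [vector_field3d].
#' @export
perturb_phantom <- function(field, angular_noise_sd, seed) {
  if (angular_noise_sd < 0) stop_invalid("angular_noise_sd must be >= 0")
  if (angular_noise_sd == 0) return(field)
  idx <- which(field$mask)
  n <- length(idx)
  with_seed(seed, {
    m <- cbind(field$mx[idx], field$my[idx], field$mz[idx])
    mag <- sqrt(rowSums(m^2))
    u <- m / pmax(mag, 1e-300)
    # random unit axis perpendicular to u
    a <- matrix(stats::rnorm(3 * n), n, 3)
    a <- a - u * rowSums(a * u)
    a <- a / pmax(sqrt(rowSums(a^2)), 1e-300)
    ang <- stats::rnorm(n, 0, angular_noise_sd)
    # Rodrigues rotation of u about axis a (a is perpendicular to u)
    axu <- cbind(a[, 2] * u[, 3] - a[, 3] * u[, 2],
                 a[, 3] * u[, 1] - a[, 1] * u[, 3],
                 a[, 1] * u[, 2] - a[, 2] * u[, 1])
    un <- u * cos(ang) + axu * sin(ang)
    un <- un * mag
    mx <- field$mx; my <- field$my; mz <- field$mz
    mx[idx] <- un[, 1]; my[idx] <- un[, 2]; mz[idx] <- un[, 3]
    vector_field3d(mx, my, mz, field$voxel_size, field$mask, field$origin)
  })
}
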