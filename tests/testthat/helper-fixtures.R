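# Shared fixtures, built in code at test time.

MS_MAGNETITE <- 4.80768e5

# Scaled-down spearhead for fast tests (same shape class as the full
# geometry, fewer slabs / coarser voxels).
mini_spearhead <- function(n_frustrums = 30) {
  build_spearhead_geometry(n_frustrums = n_frustrums)
}

# Straight-axis vortex phantom on a coarse grid.
straight_phantom <- function(voxel = 80e-9, flip = NULL, tip_rev = FALSE,
                             sense = 1L) {
  geo <- mini_spearhead()
  sp <- phantom_spec(rbind(c(0, 0, 0), c(0, 0, geo$long_axis_length)),
                     polarity_flip_position = flip,
                     circulation_sense = sense,
                     tip_mz_reversal = tip_rev)
  make_vortex_phantom(geo, sp, MS_MAGNETITE, voxel)
}

# Curved-core phantom mimicking the observed trajectory: starts at one edge
# of the base, passes the centre, exits near the tip.
curved_phantom <- function(voxel = 40e-9, flip = 0.5, tip_rev = TRUE,
                           pad = 1L) {
  geo <- build_spearhead_geometry()
  sp <- phantom_spec(rbind(c(-3e-7, 0, 1e-7),
                           c(0, 0, 1.2e-6),
                           c(1e-7, 0, 2.1e-6)),
                     polarity_flip_position = flip,
                     tip_mz_reversal = tip_rev)
  list(geometry = geo, spec = sp,
       field = make_vortex_phantom(geo, sp, MS_MAGNETITE, voxel, pad = pad))
}

# Cubic all-true mask of n voxels edge h.
cube_mask <- function(n, h) {
  m <- array(TRUE, c(n, n, n))
  attr(m, "voxel_size") <- h
  attr(m, "origin") <- -c(n, n, n) / 2 * h
  m
}

# Voxelized sphere of radius r at voxel h (stack of circular slabs).
sphere_mask <- function(r, h, nsl = 40) {
  zb <- seq(0, 2 * r, length.out = nsl + 1)
  radii <- sqrt(pmax(r^2 - (zb - r)^2, (1e-4 * r)^2))
  geo <- particle_geometry(diff(zb), radii, 1)
  voxelize(geo, h)
}

# Random unit-vector field on a mask (seeded).
random_field <- function(mask, seed = 1, M_s = 1) {
  random_initialize(mask, M_s, seed = seed)
}

# Dense ray-march projection oracle: integrates M . b along rays through
# each image pixel at `oversample` times the voxel sampling, independent of
# the package's rotate-and-sum projector.
raymarch_project <- function(field, b, oversample = 4) {
  b <- b / sqrt(sum(b^2))
  v <- c(0, 1, 0) - b[2] * b
  if (sqrt(sum(v^2)) < 1e-8) v <- c(0, 0, 1) - b[3] * b
  v <- v / sqrt(sum(v^2))
  w <- c(b[2] * v[3] - b[3] * v[2], b[3] * v[1] - b[1] * v[3],
         b[1] * v[2] - b[2] * v[1])
  d <- dim(field$mx)
  h <- field$voxel_size
  cx <- (d + 1) / 2
  nstep <- ceiling(max(d) * 1.8 * oversample)
  ts <- seq(-max(d) * 0.9, max(d) * 0.9, length.out = nstep)
  dt <- (ts[2] - ts[1])
  out <- matrix(0, d[2], d[3])
  tri <- function(A, p1, p2, p3) {
    # trilinear sample of array A at fractional indices (vectors)
    i0 <- floor(p1); j0 <- floor(p2); k0 <- floor(p3)
    f1 <- p1 - i0; f2 <- p2 - j0; f3 <- p3 - k0
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      ii <- i0 + dx; jj <- j0 + dy; kk <- k0 + dz
      wt <- (if (dx == 0) 1 - f1 else f1) * (if (dy == 0) 1 - f2 else f2) *
        (if (dz == 0) 1 - f3 else f3)
      ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
      wt[!ok] <- 0; ii[!ok] <- 1L; jj[!ok] <- 1L; kk[!ok] <- 1L
      acc <- acc + wt * A[cbind(ii, jj, kk)]
    }
    acc
  }
  for (iy in seq_len(d[2])) for (iz in seq_len(d[3])) {
    p0 <- cx + (iy - cx[2]) * v + (iz - cx[3]) * w
    p1 <- p0[1] + ts * b[1]
    p2 <- p0[2] + ts * b[2]
    p3 <- p0[3] + ts * b[3]
    sig <- b[1] * tri(field$mx, p1, p2, p3) +
      b[2] * tri(field$my, p1, p2, p3) +
      b[3] * tri(field$mz, p1, p2, p3)
    out[iy, iz] <- sum(sig) * dt * h
  }
  out
}
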