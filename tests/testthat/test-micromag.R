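magnetite_identity <- function()
  material_params(MS_MAGNETITE, -1.32658e4, 1.33487e-11)

test_that("uniformly magnetized bodies reproduce the closed-form energy terms", {
  n <- 16; h <- 5e-9
  mask <- cube_mask(n, h)
  pars <- magnetite_identity()
  V <- n^3 * h^3
  mu0 <- mag_constants()$mu0
  f <- uniform_initialize(mask, MS_MAGNETITE, c(0, 0, 1))
  ef <- effective_field(f, pars)
  expect_equal(ef$energy$exchange, 0)
  # cube demag factor 1/3: E = mu0/6 Ms^2 V
  expect_equal(ef$energy$demagnetizing, mu0 / 6 * MS_MAGNETITE^2 * V,
               tolerance = 0.01)
  # cubic anisotropy: [100] is the hard direction for K1 < 0 (density 0),
  # [111] the easy one (density K1/3)
  expect_equal(ef$energy$anisotropy, 0)
  f111 <- uniform_initialize(mask, MS_MAGNETITE, c(1, 1, 1))
  e111 <- effective_field(f111, pars)$energy$anisotropy
  expect_equal(e111 / V, -1.32658e4 / 3, tolerance = 1e-10)
  expect_lt(e111, 0)
  # energy breakdown sums to the total
  expect_equal(ef$energy$total,
               ef$energy$exchange + ef$energy$anisotropy +
                 ef$energy$demagnetizing + ef$energy$zeeman,
               tolerance = 1e-12)
})

test_that("a uniformly magnetized sphere has demag factor 1/3 within 2%", {
  h <- 1.2e-8
  mask <- sphere_mask(2e-7, h)   # ~33 voxels across the diameter
  mu0 <- mag_constants()$mu0
  f <- uniform_initialize(mask, MS_MAGNETITE, c(0, 0, 1))
  ef <- effective_field(f, magnetite_identity())
  V <- sum(mask) * h^3
  N_eff <- ef$energy$demagnetizing / (mu0 / 2 * MS_MAGNETITE^2 * V)
  expect_equal(N_eff, 1 / 3, tolerance = 0.02)
})

test_that("demagnetizing energy scales with Ms^2 and is non-negative", {
  mask <- cube_mask(8, 1e-8)
  p1 <- material_params(1e5, -1e4, 1.3e-11)
  p2 <- material_params(2e5, -1e4, 1.3e-11)
  f1 <- random_initialize(mask, 1e5, seed = 4)
  f2 <- giantmag:::field_lincomb(2, f1)
  e1 <- effective_field(f1, p1)$energy$demagnetizing
  e2 <- effective_field(f2, p2)$energy$demagnetizing
  expect_equal(e2, 4 * e1, tolerance = 1e-10)
  expect_gt(e1, 0)
  # exchange is non-negative for a random state
  expect_gte(effective_field(f1, p1)$energy$exchange, 0)
})

test_that("rotating the crystal frame together with the magnetization leaves the anisotropy energy invariant", {
  mask <- cube_mask(6, 1e-8)
  R <- crystal_orientation_113()
  pars_rot <- material_params(MS_MAGNETITE, -1.32658e4, 1.33487e-11, R)
  pars_id <- magnetite_identity()
  for (u in list(c(0, 0, 1), c(1, 0, 0), c(1, 1, 1) / sqrt(3))) {
    # sample direction u under rotated frame == crystal direction R u
    f_rot <- uniform_initialize(mask, MS_MAGNETITE, u)
    f_id <- uniform_initialize(mask, MS_MAGNETITE, as.vector(R %*% u))
    e_rot <- effective_field(f_rot, pars_rot)$energy$anisotropy
    e_id <- effective_field(f_id, pars_id)$energy$anisotropy
    expect_equal(e_rot, e_id, tolerance = 1e-8)
  }
})

test_that("orientation helper produces proper rotations with the requested alignment", {
  R <- crystal_orientation_113()
  expect_equal(det(R), 1, tolerance = 1e-12)
  expect_equal(crossprod(R), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  # sample z axis is [113] in crystal coordinates
  expect_equal(R[, 3], c(1, 1, 3) / sqrt(11), tolerance = 1e-12,
               ignore_attr = TRUE)
  # [111] lies in the sample x-z plane: its sample-frame y component is 0
  v111 <- c(1, 1, 1) / sqrt(3)
  sample_coords <- t(R) %*% v111
  expect_equal(sample_coords[2], 0, tolerance = 1e-12)
  expect_error(material_params(1e5, 0, 1e-11, diag(3) * 2), "proper rotation")
})

test_that("a small magnetite cube relaxes to a quasi-uniform single-domain state and never raises the energy", {
  mask <- cube_mask(8, 5e-9)       # 40 nm cube, below the vortex threshold
  pars <- magnetite_identity()
  init <- uniform_initialize(mask, MS_MAGNETITE, c(1, 1, 1))
  res <- minimize(init, pars, tolerance = 1e-4, max_iter = 400, quiet = TRUE)
  expect_true(all(diff(res$energy_history) <=
                    1e-11 * abs(res$energy_history[1])))
  m <- net_moment(res$field)
  # moment stays near the saturation value (quasi-uniform)
  expect_gt(sqrt(sum(m^2)) / (MS_MAGNETITE * sum(mask) * (5e-9)^3), 0.97)
})

test_that("vortex initialization honors core strength sign and rejects empty masks", {
  mask <- cube_mask(10, 2e-8)
  vp <- vortex_initialize(mask, MS_MAGNETITE, core_strength = 2)
  vm <- vortex_initialize(mask, MS_MAGNETITE, core_strength = -2)
  # mirror state: M_z negated everywhere, circulation unchanged
  expect_equal(vm$mz, -vp$mz, tolerance = 1e-12)
  expect_equal(vm$mx, vp$mx, tolerance = 1e-12)
  # core polarity follows the sign on the axis
  d <- dim(mask)
  expect_gt(vp$mz[d[1] / 2, d[2] / 2, d[3] / 2], 0)
  expect_lt(vm$mz[d[1] / 2, d[2] / 2, d[3] / 2], 0)
  empty <- array(FALSE, c(4, 4, 4)); attr(empty, "voxel_size") <- 1e-8
  expect_error(vortex_initialize(empty, MS_MAGNETITE), "empty")
  expect_error(random_initialize(empty, MS_MAGNETITE), "empty")
})

test_that("seeded random states are reproducible", {
  mask <- cube_mask(6, 1e-8)
  a <- random_initialize(mask, MS_MAGNETITE, seed = 7)
  b <- random_initialize(mask, MS_MAGNETITE, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, random_initialize(mask, MS_MAGNETITE, seed = 8)))
  mag <- field_magnitude(a)
  expect_lt(max(abs(mag[mask] / MS_MAGNETITE - 1)), 1e-12)
})

test_that("an easy-axis single-domain particle shows a square hysteresis loop", {
  # elongated magnetite block: shape anisotropy keeps the loop square
  mask <- array(FALSE, c(6, 6, 14))
  mask[2:5, 2:5, 2:13] <- TRUE
  attr(mask, "voxel_size") <- 5e-9
  pars <- magnetite_identity()
  hl <- hysteresis_loop(mask, pars, axis = c(0, 0, 1), B_max = 0.3,
                        B_step = 0.05, tolerance = 1e-3, max_iter = 300)
  expect_gt(hl$summary$squareness, 0.9)
  # the elongated block switches by shape anisotropy well below saturation
  expect_true(is.finite(hl$summary$B_c))
  expect_gt(hl$summary$B_c, 0)
  expect_lt(hl$summary$B_c, 0.3)
  expect_error(hysteresis_loop(mask, pars, B_max = 0.01, B_step = 0.02),
               "exceed")
  # symmetric protocol: M(-B) ~ -M(B) across branches
  dn <- subset(hl$loop, branch == "descending")
  up <- subset(hl$loop, branch == "ascending")
  expect_equal(dn$moment, -rev(up$moment), tolerance = 0.1)
})

test_that("susceptibility of a near-spherical isotropic particle is isotropic", {
  h <- 1.5e-8
  mask <- sphere_mask(1.5e-7, h, nsl = 40)   # 20 voxels across the diameter
  pars <- material_params(MS_MAGNETITE, -1.32658e4, 1.33487e-11)
  gs <- minimize(uniform_initialize(mask, MS_MAGNETITE, c(0, 0, 1)), pars,
                 tolerance = 1e-3, max_iter = 300, quiet = TRUE)
  chi <- susceptibility(gs$field, pars, probe_field = 1e-3,
                        tolerance = 1e-3, max_iter = 800)
  expect_gt(min(chi), 0)
  # equal within 10%, up to voxelization roughness of the sphere surface
  expect_lt(max(chi) / min(chi), 1.15)
})

test_that("growing a thin disc in one slab gives an in-plane magnetized state", {
  mask <- array(FALSE, c(14, 14, 3))
  g <- expand.grid(i = 1:14, j = 1:14)
  inside <- (g$i - 7.5)^2 + (g$j - 7.5)^2 <= 6.5^2
  for (k in 2) mask[cbind(g$i[inside], g$j[inside], k)] <- TRUE
  attr(mask, "voxel_size") <- 1e-8
  pars <- magnetite_identity()
  gr <- growth_simulation(mask, pars, "base-up", slab_thickness = 1e-8,
                          seed = 5, tolerance = 1e-3, max_iter = 400)
  m <- net_moment(gr$final)
  mz_frac <- abs(m[3]) / sqrt(sum(m^2))
  # in-plane dominated; z component small
  in_plane <- sqrt(sum(gr$final$mx^2 + gr$final$my^2))
  axial <- sqrt(sum(gr$final$mz^2))
  expect_gt(in_plane, 3 * axial)
  expect_error(growth_simulation(mask, pars, "base-up",
                                 slab_thickness = 1.5e-8, seed = 1),
               "multiple")
})
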