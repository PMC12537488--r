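test_that("uniform slab viewed along its magnetization gives thickness times M", {
  n <- 16; h <- 20e-9
  mask <- array(FALSE, c(n, n, n))
  mask[, , 5:8] <- TRUE               # slab 4 voxels thick in z
  attr(mask, "voxel_size") <- h
  Ms <- 1e5
  f <- uniform_initialize(mask, Ms, c(0, 0, 1))
  img <- xmcd_project(f, c(0, 0, 1))
  # central pixels: line integral = Ms * t where t = 4 h... beam along z:
  # every (row, col) pixel covered by the slab sees the full thickness
  centre <- img[5:12, 5:12]
  expect_equal(max(abs(centre - Ms * 4 * h)) / (Ms * 4 * h), 0, tolerance = 0.02)
})

test_that("projection matches a dense ray-march oracle within 1%", {
  # band-limited field on a sphere: resolved on the grid, so the two
  # discretizations of the same line integral must agree closely
  msk <- sphere_mask(2.4e-7, 30e-9)
  d <- dim(msk); g <- grid_coordinates(msk)
  L <- 4.8e-7
  X <- array(g$x, d)
  Y <- array(rep(g$y, each = d[1]), d)
  Z <- array(rep(g$z, each = d[1] * d[2]), d)
  f <- vector_field3d((sin(2 * pi * Z / L) + 0.3 * cos(2 * pi * Y / L)) * 1e5,
                      cos(2 * pi * X / L) * 1e5,
                      0.5 * sin(2 * pi * (X + Y) / L) * 1e5,
                      30e-9, msk)
  for (b in list(c(1, 0, 0), c(cos(0.4), 0, sin(0.4)),
                 c(0.5, 0.5, sqrt(0.5)))) {
    img <- xmcd_project(f, b)
    oracle <- raymarch_project(f, b, oversample = 4)
    expect_lt(sqrt(sum((img - oracle)^2)) / sqrt(sum(oracle^2)), 0.01)
  }
})

test_that("charge projection reproduces simple solids and the ray-march oracle", {
  h <- 25e-9
  msk <- sphere_mask(2e-7, h)
  chg <- charge_project(msk, c(1, 0, 0))
  # max projected thickness of a sphere is its diameter
  expect_equal(max(chg), 4e-7, tolerance = 0.05)
  # cylinder side-on: centre value = 2r
  r <- 2e-7
  geo <- particle_geometry(rep(2e-7, 5), rep(r, 6), 1)
  mc <- voxelize(geo, 40e-9)
  chg2 <- charge_project(mc, c(1, 0, 0))
  expect_equal(max(chg2), 2 * r, tolerance = 0.05)
  # oracle comparison via a unit field along one component
  f <- uniform_initialize(msk, 1, c(1, 0, 0))
  img <- xmcd_project(f, c(1, 0, 0))
  oracle <- raymarch_project(f, c(1, 0, 0))
  expect_lt(sqrt(sum((img - oracle)^2)) / sqrt(sum(oracle^2)), 0.01)
})

test_that("projection is linear in the field", {
  p1 <- straight_phantom(voxel = 80e-9)
  p2 <- perturb_phantom(p1, 0.3, 5)
  b <- c(cos(0.3), 0, sin(0.3))
  lhs <- xmcd_project(giantmag:::field_lincomb(2, p1, -0.5, p2), b)
  rhs <- 2 * xmcd_project(p1, b) - 0.5 * xmcd_project(p2, b)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("reversing the beam negates the XMCD map and preserves the charge map", {
  ph <- straight_phantom(voxel = 80e-9)
  b <- c(cos(0.25), 0, sin(0.25))
  f <- xmcd_project(ph, b)
  r <- xmcd_project(ph, -b)
  # beam reversal flips the image horizontal axis along with the sign
  expect_equal(r[, rev(seq_len(ncol(r)))], -f, tolerance = 1e-8)
  c1 <- charge_project(ph$mask, b)
  c2 <- charge_project(ph$mask, -b)
  expect_equal(c2[, rev(seq_len(ncol(c2)))], c1, tolerance = 1e-8)
})

test_that("tilt series bookkeeping matches the acquisition arithmetic", {
  # the first-axis angular range of the experiment spans 74 one-degree steps
  angles <- seq(-30, 43, by = 1)
  expect_length(angles, 74)
  ph <- straight_phantom(voxel = 80e-9)
  ts <- simulate_tilt_series(ph, "first", seq(-30, 40, by = 10), seed = 3)
  expect_s3_class(ts, "tilt_series")
  expect_length(ts$images, 8)
  expect_error(simulate_tilt_series(ph, "first", c(-95, 0), seed = 1), "within")
  expect_error(tilt_series(ts$images, rev(ts$angles), "first", 1e-8),
               "strictly increasing")
})

test_that("noiseless unshifted series equals direct projections", {
  ph <- straight_phantom(voxel = 80e-9)
  ts <- simulate_tilt_series(ph, "first", c(-20, 0, 25), seed = 1)
  for (i in seq_along(ts$angles)) {
    a <- ts$angles[i] * pi / 180
    direct <- xmcd_project(ph, c(cos(a), 0, sin(a)))
    expect_equal(ts$images[[i]], direct, tolerance = 1e-10)
  }
})

test_that("series are deterministic under a fixed seed and reproducible noise/shifts", {
  ph <- straight_phantom(voxel = 80e-9)
  t1 <- simulate_tilt_series(ph, "first", c(-10, 0, 10), noise_sd = 0.01,
                             shift_sd = 1, seed = 9)
  t2 <- simulate_tilt_series(ph, "first", c(-10, 0, 10), noise_sd = 0.01,
                             shift_sd = 1, seed = 9)
  expect_identical(t1$images, t2$images)
  expect_identical(t1$applied_shifts, t2$applied_shifts)
  t3 <- simulate_tilt_series(ph, "first", c(-10, 0, 10), noise_sd = 0.01,
                             shift_sd = 1, seed = 10)
  expect_false(identical(t1$images, t3$images))
})

test_that("zero-tilt image of the second series is the 90-degree-rotated zero-tilt image of the first", {
  cp <- curved_phantom(voxel = 80e-9)
  s1 <- simulate_tilt_series(cp$field, "first", c(-5, 0, 5), seed = 1)
  s2 <- simulate_tilt_series(cp$field, "second", c(-5, 0, 5), seed = 2)
  A <- s1$charge_images[[2]]
  B <- s2$charge_images[[2]]
  # in-plane 90-degree rotation maps one frame onto the other
  rotB <- t(B)[rev(seq_len(ncol(B))), , drop = FALSE]
  expect_equal(dim(rotB), dim(A))
  expect_equal(rotB, A, tolerance = 1e-8)
})

test_that("forward projector and back-projector are exact adjoints", {
  set.seed(11)
  d <- c(16L, 16L, 16L)
  for (angle in c(-33.3, 0, 12.5, 61)) {
    geom <- giantmag:::.tilt_geometry(d[1], d[3], angle)
    V <- array(rnorm(prod(d)), d)
    I <- matrix(rnorm(d[2] * d[3]), d[2], d[3])
    lhs <- sum(giantmag:::.project_scalar_tilt(V, geom) * I)
    rhs <- sum(V * giantmag:::.backproject_scalar_tilt(I, geom, d))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})
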