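make_pair <- function(field, angles1, angles2, noise_sd = 0, shift_sd = 0,
                      seed = 1) {
  list(s1 = simulate_tilt_series(field, "first", angles1, noise_sd = noise_sd,
                                 shift_sd = shift_sd, seed = seed),
       s2 = simulate_tilt_series(field, "second", angles2, noise_sd = noise_sd,
                                 shift_sd = shift_sd, seed = seed + 1000))
}

test_that("alignment recovers known shifts", {
  cp <- curved_phantom(voxel = 80e-9, pad = 5L)
  ts <- simulate_tilt_series(cp$field, "first", seq(-30, 30, by = 5),
                             shift_sd = 1.5, seed = 21)
  al <- align_series(ts)
  err <- al$recovered_shifts - ts$applied_shifts
  # relative alignment is what matters: a common offset is unobservable
  err[, 1] <- err[, 1] - mean(err[, 1])
  err[, 2] <- err[, 2] - mean(err[, 2])
  expect_lt(max(abs(err[, 2])), 0.9)      # horizontal: integer cross-correlation
  expect_lt(max(abs(err[, 1])), 0.2)      # vertical: subpixel mass alignment
})

test_that("already-aligned series yields near-zero recovered shifts", {
  cp <- curved_phantom(voxel = 80e-9)
  ts <- simulate_tilt_series(cp$field, "first", seq(-20, 20, by = 10), seed = 2)
  al <- align_series(ts)
  expect_lt(max(abs(al$recovered_shifts)), 0.2)
})

test_that("subpixel vertical shifts are recovered within 0.1 px", {
  cp <- curved_phantom(voxel = 80e-9)
  ts <- simulate_tilt_series(cp$field, "first", seq(-10, 10, by = 10), seed = 3)
  shifted <- ts
  true_dv <- c(0.4, -0.35, 0.25)
  for (i in seq_along(ts$images)) {
    shifted$images[[i]] <- giantmag:::.shift_image(ts$images[[i]], true_dv[i], 0)
    shifted$charge_images[[i]] <-
      giantmag:::.shift_image(ts$charge_images[[i]], true_dv[i], 0)
  }
  al <- align_series(shifted)
  rec <- al$recovered_shifts[, 1]
  expect_lt(max(abs((rec - mean(rec)) - (true_dv - mean(true_dv)))), 0.1)
})

test_that("featureless series triggers an alignment diagnostic", {
  imgs <- replicate(3, matrix(1, 8, 8), simplify = FALSE)
  ts <- tilt_series(imgs, c(-1, 0, 1), "first", 1e-8, charge_images = imgs)
  expect_error(align_series(ts), "featureless")
})

test_that("axis registration recovers a constructed offset and disambiguates the rotation sense", {
  cp <- curved_phantom(voxel = 80e-9)
  pair <- make_pair(cp$field, c(-5, 0, 5), c(-5, 0, 5))
  reg0 <- register_axes(pair$s1, pair$s2)
  expect_equal(unname(reg0$offset), c(0, 0))
  s2s <- pair$s2
  for (i in seq_along(s2s$images)) {
    s2s$images[[i]] <- giantmag:::.shift_image(s2s$images[[i]], 3, -2)
    s2s$charge_images[[i]] <- giantmag:::.shift_image(s2s$charge_images[[i]], 3, -2)
  }
  reg <- register_axes(pair$s1, s2s)
  expect_equal(reg$rotation_sense, reg0$rotation_sense)
  # the shift applied in the rotated frame appears rotated in series1's frame
  expect_equal(sort(abs(unname(reg$offset))), c(2, 3))
  # the correct rotation hypothesis wins clearly
  expect_gt(max(reg$peak_correlations), 1.2 * min(reg$peak_correlations))
  expect_error(register_axes(pair$s1,
                             simulate_tilt_series(cp$field, "second",
                                                  c(20, 25), seed = 1)),
               "near-zero")
})

test_that("all-zero projections reconstruct to the zero field with zero error", {
  cp <- curved_phantom(voxel = 80e-9)
  pair <- make_pair(cp$field, seq(-30, 30, 10), seq(-30, 30, 10))
  for (i in seq_along(pair$s1$images)) pair$s1$images[[i]][] <- 0
  for (i in seq_along(pair$s2$images)) pair$s2$images[[i]][] <- 0
  rec <- reconstruct_vector(pair$s1, pair$s2, cp$field$mask, n_iterations = 3)
  expect_equal(max(abs(rec$field$mx)), 0)
  expect_equal(rec$error_history, rep(0, 1))
})

test_that("noiseless wide-coverage dual-axis round trip recovers the phantom", {
  cp <- curved_phantom(voxel = 80e-9)
  angles <- seq(-70, 70, by = 5)
  pair <- make_pair(cp$field, angles, angles)
  rec <- reconstruct_vector(pair$s1, pair$s2, cp$field$mask, n_iterations = 10)
  expect_equal(rec$iteration_count, 10)
  # error strictly non-increasing
  expect_true(all(diff(rec$error_history) <= 1e-9 * rec$error_history[1]))
  relerr <- sqrt(sum((rec$field$mx - cp$field$mx)^2 +
                     (rec$field$my - cp$field$my)^2 +
                     (rec$field$mz - cp$field$mz)^2)) /
    sqrt(sum(cp$field$mx^2 + cp$field$my^2 + cp$field$mz^2))
  expect_lt(relerr, 0.35)   # coarse grid, 5-degree sampling
  # re-projection reproduces the data: residual far below the signal
  expect_lt(rec$error_history[length(rec$error_history)],
            1e-2 * rec$error_history[1])
})

test_that("limited-wedge reconstruction elongates the point spread along the beam axis", {
  # point-spread function of a single-voxel magnetic impulse under the
  # restricted experimental tilt ranges, reconstructed without a mask
  n <- 20L
  h <- 40e-9
  mask <- cube_mask(n, h)
  mx <- array(0, c(n, n, n)); my <- mx; mz <- mx
  c0 <- n / 2
  mx[c0, c0, c0] <- 1e5; my[c0, c0, c0] <- 1e5; mz[c0, c0, c0] <- 1e5
  imp <- vector_field3d(mx, my, mz, h, mask)
  pair <- make_pair(imp, seq(-30, 43, by = 2), seq(-42, 34, by = 2))
  rec <- reconstruct_vector(pair$s1, pair$s2, mask, n_iterations = 10)
  w <- field_magnitude(rec$field)^2
  width <- function(axis) {
    idx <- switch(axis,
                  x = array(seq_len(n), dim(w)),
                  y = array(rep(seq_len(n), each = n), dim(w)),
                  z = array(rep(seq_len(n), each = n * n), dim(w)))
    mu <- sum(idx * w) / sum(w)
    sqrt(sum((idx - mu)^2 * w) / sum(w))
  }
  wx <- width("x"); wy <- width("y"); wz <- width("z")
  # beam-direction (x) spread exceeds both transverse spreads
  expect_gt(wx / wy, 1.2)
  expect_gt(wx / wz, 1.2)
  # in the well-sampled transverse plane the point spread stays compact
  # (full width of a Gaussian of sd wy is ~2.35 wy voxels)
  expect_lt(wy, 1.5)
  expect_lt(wz, 1.5)
})

test_that("mismatched grids are rejected", {
  cp <- curved_phantom(voxel = 80e-9)
  pair <- make_pair(cp$field, c(-10, 0, 10), c(-10, 0, 10))
  wrong <- array(TRUE, dim(cp$field$mx) + c(0, 2, 0))
  attr(wrong, "voxel_size") <- cp$field$voxel_size
  expect_error(reconstruct_vector(pair$s1, pair$s2, wrong), "do not match")
  expect_error(reconstruct_vector(pair$s2, pair$s2, cp$field$mask), "first")
})
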