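#' Micromagnetic material parameters
#'
#' @param M_s saturation magnetization (A/m).
#' @param K_1 first cubic magnetocrystalline anisotropy constant (J/m^3);
#'   negative for magnetite, making <111> the easy axes.
#' @param A_ex exchange constant (J/m).
#' @param crystal_orientation 3x3 proper rotation whose columns are the
#'   sample-frame `x`, `y`, `z` axes expressed in cube-axis (crystal)
#'   coordinates; identity aligns the cube axes with the sample frame.
#' @return An object of class `material_params`.
#' @export
material_params <- function(M_s, K_1, A_ex, crystal_orientation = diag(3)) {
  if (M_s <= 0) stop_invalid("M_s must be positive")
  if (A_ex <= 0) stop_invalid("A_ex must be positive")
  R <- as.matrix(crystal_orientation)
  if (!isTRUE(all.equal(dim(R), c(3L, 3L))) ||
      abs(det(R) - 1) > 1e-9 ||
      max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop_invalid("crystal_orientation must be a proper rotation (det +1, orthonormal)")
  structure(list(M_s = M_s, K_1 = K_1, A_ex = A_ex,
                 crystal_orientation = R), class = "material_params")
}

#' Magnetite parameters at room temperature
#'
#' `M_s = 4.80768e5` A/m, `K_1 = -1.32658e4` J/m^3,
#' `A_ex = 1.33487e-11` J/m.
#'
#' @param crystal_orientation see [material_params()]; the default
#'   [crystal_orientation_113()] places \[113\] along the particle long axis
#'   with \[111\] in the x-z plane, the configuration that best matches the
#'   spearhead observations.
#' @return A [material_params].
#' @export
magnetite_params <- function(crystal_orientation = crystal_orientation_113()) {
  material_params(M_s = 4.80768e5, K_1 = -1.32658e4, A_ex = 1.33487e-11,
                  crystal_orientation = crystal_orientation)
}

#' Crystallographic orientation with a chosen direction along z
#'
#' Builds the rotation placing crystal direction `z_dir` along the sample
#' `z` axis with `x_dir` (projected) in the sample x-z plane.
#'
#' @param z_dir crystal direction (Miller indices) for the long axis.
#' @param x_dir crystal direction whose projection defines sample `x`.
#' @return 3x3 rotation matrix (columns = sample axes in crystal
#'   coordinates).
#' @export
crystal_orientation_axes <- function(z_dir, x_dir) {
  e3 <- z_dir / sqrt(sum(z_dir^2))
  e1 <- x_dir - sum(x_dir * e3) * e3
  if (sqrt(sum(e1^2)) < 1e-12)
    stop_invalid("x_dir must not be parallel to z_dir")
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  cbind(e1, e2, e3)
}

#' @rdname crystal_orientation_axes
#' @export
crystal_orientation_113 <- function() {
  crystal_orientation_axes(c(1, 1, 3), c(1, 1, 1))
}

# ---- Newell cell-averaged demagnetizing tensor -----------------------------

# Newell (1993) auxiliary functions for the cell-averaged demag tensor of
# cuboid cells.  Vectorized; singular terms are defined by continuity
# (each is multiplied by a prefactor that vanishes at the singularity).
.newell_f <- function(x, y, z) {
  x2 <- x^2; y2 <- y^2; z2 <- z^2
  R <- sqrt(x2 + y2 + z2)
  atq <- function(num, den) ifelse(den != 0, atan(num / den), 0)
  t1 <- ifelse(x2 + z2 > 0, 0.5 * y * (z2 - x2) * asinh(y / sqrt(x2 + z2)), 0)
  t2 <- ifelse(x2 + y2 > 0, 0.5 * z * (y2 - x2) * asinh(z / sqrt(x2 + y2)), 0)
  t3 <- -x * y * z * atq(y * z, x * R)
  t1 + t2 + t3 + (1 / 6) * (2 * x2 - y2 - z2) * R
}

.newell_g <- function(x, y, z) {
  x2 <- x^2; y2 <- y^2; z2 <- z^2
  R <- sqrt(x2 + y2 + z2)
  atq <- function(num, den) ifelse(den != 0, atan(num / den), 0)
  t1 <- ifelse(x2 + y2 > 0, x * y * z * asinh(z / sqrt(x2 + y2)), 0)
  t2 <- ifelse(y2 + z2 > 0, (y / 6) * (3 * z2 - y2) * asinh(x / sqrt(y2 + z2)), 0)
  t3 <- ifelse(x2 + z2 > 0, (x / 6) * (3 * z2 - x2) * asinh(y / sqrt(x2 + z2)), 0)
  t4 <- -(z^3 / 6) * atq(x * y, z * R)
  t5 <- -(z * y2 / 2) * atq(x * z, y * R)
  t6 <- -(z * x2 / 2) * atq(y * z, x * R)
  t1 + t2 + t3 + t4 + t5 + t6 - x * y * R / 3
}

# 27-point second-difference stencil of fun over cell offsets, divided by
# 4*pi*h^3: the cell-averaged tensor element at integer offsets (I, J, K).
.newell_element <- function(fun, I, J, K, h) {
  w <- c(1, -2, 1)
  acc <- 0
  for (a in -1:1) for (b in -1:1) for (cc in -1:1)
    acc <- acc + w[a + 2] * w[b + 2] * w[cc + 2] *
      fun((I + a) * h, (J + b) * h, (K + cc) * h)
  -acc / (4 * pi * h^3)   # sign such that N(0,0,0) diag is +1/3 for a cube
}

# Demag "plan": FFTs of the 6 independent tensor components on the
# zero-padded grid, for dimensions d and voxel size h.  Padding is at least
# 2x - 1 in every dimension (no wraparound), rounded up to FFT-friendly
# sizes.
demag_plan <- function(d, h) {
  P <- vapply(d, function(n) stats::nextn(2L * n, c(2, 3, 5)), integer(1))
  offs <- function(n, p) {
    o <- seq_len(p) - 1L
    ifelse(o >= p / 2, o - p, o)          # wrapped offsets
  }
  o1 <- offs(d[1], P[1]); o2 <- offs(d[2], P[2]); o3 <- offs(d[3], P[3])
  I <- array(o1, P)
  J <- array(rep(o2, each = P[1]), P)
  K <- array(rep(o3, each = P[1] * P[2]), P)
  # only offsets within +/-(d - 1) ever reach the cropped output region
  valid <- abs(I) <= d[1] - 1 & abs(J) <= d[2] - 1 & abs(K) <= d[3] - 1
  # evaluate on the absolute-offset octant, then fill by parity:
  # Nxx is even in all arguments; Nxy odd in x and y, even in z (and
  # permutations thereof)
  oct <- function(fun, n1, n2, n3) {
    i <- rep(0:(n1 - 1), times = n2 * n3)
    j <- rep(rep(0:(n2 - 1), each = n1), times = n3)
    k <- rep(0:(n3 - 1), each = n1 * n2)
    array(.newell_element(fun, i, j, k, h), c(n1, n2, n3))
  }
  li <- function(a1, a2, a3, n1, n2) a1 + 1L + n1 * a2 + n1 * n2 * a3
  aI <- abs(I) * valid; aJ <- abs(J) * valid; aK <- abs(K) * valid
  comp <- function(fun, px, py, pz, A1, A2, A3, s1, s2, s3) {
    n1 <- max(A1) + 1L; n2 <- max(A2) + 1L; n3 <- max(A3) + 1L
    O <- oct(fun, n1, n2, n3)
    v <- array(O[li(A1, A2, A3, n1, n2)], P) * valid
    if (px) v <- v * sign(s1)
    if (py) v <- v * sign(s2)
    if (pz) v <- v * sign(s3)
    v
  }
  Nxx <- comp(.newell_f, FALSE, FALSE, FALSE, aI, aJ, aK, I, J, K)
  Nyy <- comp(.newell_f, FALSE, FALSE, FALSE, aJ, aI, aK, J, I, K)
  Nzz <- comp(.newell_f, FALSE, FALSE, FALSE, aK, aJ, aI, K, J, I)
  # g is odd in its first two arguments and even in the third, so the
  # parity signs always follow the first two (permuted) offsets
  Nxy <- comp(.newell_g, TRUE, TRUE, FALSE, aI, aJ, aK, I, J, K)
  Nxz <- comp(.newell_g, TRUE, TRUE, FALSE, aI, aK, aJ, I, K, J)
  Nyz <- comp(.newell_g, TRUE, TRUE, FALSE, aJ, aK, aI, J, K, I)
  list(P = P, d = d,
       F = lapply(list(xx = Nxx, yy = Nyy, zz = Nzz,
                       xy = Nxy, xz = Nxz, yz = Nyz), stats::fft))
}

# Demagnetizing field (A/m) of magnetization component arrays (A/m) via FFT
# convolution with the Newell tensor: H = -N * M.
.demag_field <- function(Mx, My, Mz, plan) {
  d <- plan$d; P <- plan$P
  pad <- function(A) {
    B <- array(0, P)
    B[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- A
    stats::fft(B)
  }
  FMx <- pad(Mx); FMy <- pad(My); FMz <- pad(Mz)
  Fn <- plan$F
  crop <- function(FH) {
    Re(stats::fft(FH, inverse = TRUE) / prod(P))[
      seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  }
  Hx <- -crop(Fn$xx * FMx + Fn$xy * FMy + Fn$xz * FMz)
  Hy <- -crop(Fn$xy * FMx + Fn$yy * FMy + Fn$yz * FMz)
  Hz <- -crop(Fn$xz * FMx + Fn$yz * FMy + Fn$zz * FMz)
  list(Hx, Hy, Hz)
}

# Shift an array by one voxel along an axis, zero-filling the vacated face.
.shift1 <- function(A, axis, dir) {
  d <- dim(A)
  out <- array(0, d)
  if (axis == 1) {
    if (dir > 0) out[1:(d[1] - 1), , ] <- A[2:d[1], , ]
    else out[2:d[1], , ] <- A[1:(d[1] - 1), , ]
  } else if (axis == 2) {
    if (dir > 0) out[, 1:(d[2] - 1), ] <- A[, 2:d[2], ]
    else out[, 2:d[2], ] <- A[, 1:(d[2] - 1), ]
  } else {
    if (dir > 0) out[, , 1:(d[3] - 1)] <- A[, , 2:d[3]]
    else out[, , 2:d[3]] <- A[, , 1:(d[3] - 1)]
  }
  out
}

# 6-neighbor vector Laplacian with free (Neumann) boundaries at the mask
# edge: missing neighbors contribute nothing.
.masked_laplacian <- function(A, mask) {
  L <- array(0, dim(A))
  mnum <- array(as.numeric(mask), dim(mask))
  for (axis in 1:3) for (dir in c(1, -1)) {
    Anb <- .shift1(A, axis, dir)
    ok <- mnum * .shift1(mnum, axis, dir)
    L <- L + ok * (Anb - A)
  }
  L
}

#' Effective field and energy breakdown of a micromagnetic state
#'
#' Evaluates the standard micromagnetic energy functional on the voxel grid:
#' exchange (6-neighbor discrete Laplacian, free boundaries at the mask
#' edge), cubic magnetocrystalline anisotropy (evaluated in the crystal
#' frame), the demagnetizing interaction (FFT convolution with the Newell
#' cell-averaged tensor, zero-padded against wraparound), and the Zeeman
#' term.  The returned effective field is the negative energy gradient,
#' `H_eff = -(1 / mu0 Ms V_cell) dE/dm`, so the torque `m x H_eff` drives
#' the minimizer.
#'
#' @param field a [vector_field3d], normalized (|M| = M_s inside the mask).
#' @param params a [material_params].
#' @param applied external flux density, length-3 (T).
#' @param plan optional precomputed demag plan (internal reuse).
#' @return A list with `H` (list of 3 arrays, A/m) and `energy` (list with
#'   `exchange`, `anisotropy`, `demagnetizing`, `zeeman`, `total`, J).
#' @export
effective_field <- function(field, params, applied = c(0, 0, 0), plan = NULL) {
  h <- field$voxel_size
  if (h > 40e-9 + 1e-15)
    warning("voxel_size exceeds 40 nm; exchange lengths are under-resolved")
  Ms <- params$M_s
  mag <- field_magnitude(field)
  if (max(abs(mag[field$mask] / Ms - 1)) > 1e-3)
    stop_invalid("field must be normalized to |M| = M_s inside the mask")
  mask <- field$mask
  V <- h^3
  m <- list(field$mx / Ms, field$my / Ms, field$mz / Ms)
  for (c in 1:3) m[[c]][!mask] <- 0

  # exchange
  cex <- 2 * params$A_ex / (.mu0 * Ms * h^2)
  Hx <- cex * .masked_laplacian(m[[1]], mask)
  Hy <- cex * .masked_laplacian(m[[2]], mask)
  Hz <- cex * .masked_laplacian(m[[3]], mask)
  # equals the non-negative pairwise form (A V / h^2) sum_pairs |m_i - m_j|^2
  E_ex <- -(.mu0 * Ms * V / 2) * sum(m[[1]] * Hx + m[[2]] * Hy + m[[3]] * Hz)

  # cubic anisotropy in the crystal frame
  R <- params$crystal_orientation        # columns: sample axes in crystal frame
  a1 <- R[1, 1] * m[[1]] + R[1, 2] * m[[2]] + R[1, 3] * m[[3]]
  a2 <- R[2, 1] * m[[1]] + R[2, 2] * m[[2]] + R[2, 3] * m[[3]]
  a3 <- R[3, 1] * m[[1]] + R[3, 2] * m[[2]] + R[3, 3] * m[[3]]
  K1 <- params$K_1
  E_an <- K1 * V * sum((a1^2 * a2^2 + a2^2 * a3^2 + a3^2 * a1^2)[mask])
  # dE/da_i = 2 K1 a_i (a_j^2 + a_k^2); field = -(1/mu0 Ms) R^T dE/da
  g1 <- 2 * K1 * a1 * (a2^2 + a3^2)
  g2 <- 2 * K1 * a2 * (a1^2 + a3^2)
  g3 <- 2 * K1 * a3 * (a1^2 + a2^2)
  ca <- -1 / (.mu0 * Ms)
  Hx <- Hx + ca * (R[1, 1] * g1 + R[2, 1] * g2 + R[3, 1] * g3)
  Hy <- Hy + ca * (R[1, 2] * g1 + R[2, 2] * g2 + R[3, 2] * g3)
  Hz <- Hz + ca * (R[1, 3] * g1 + R[2, 3] * g2 + R[3, 3] * g3)

  # demagnetizing
  if (is.null(plan)) plan <- demag_plan(dim(field$mx), h)
  Hd <- .demag_field(field$mx, field$my, field$mz, plan)
  E_d <- -(.mu0 / 2) * V *
    sum(field$mx * Hd[[1]] + field$my * Hd[[2]] + field$mz * Hd[[3]])
  Hx <- Hx + Hd[[1]]; Hy <- Hy + Hd[[2]]; Hz <- Hz + Hd[[3]]

  # Zeeman
  E_z <- -V * sum(field$mx * applied[1] + field$my * applied[2] +
                    field$mz * applied[3])
  Hx <- Hx + applied[1] / .mu0
  Hy <- Hy + applied[2] / .mu0
  Hz <- Hz + applied[3] / .mu0

  Hx[!mask] <- 0; Hy[!mask] <- 0; Hz[!mask] <- 0
  energy <- list(exchange = E_ex, anisotropy = E_an, demagnetizing = E_d,
                 zeeman = E_z, total = E_ex + E_an + E_d + E_z)
  list(H = list(Hx, Hy, Hz), energy = energy)
}

#' Relax a micromagnetic state by damped gradient descent
#'
#' Projected gradient flow on the unit sphere: each step moves every moment
#' toward its effective field direction (the tangential component of the
#' field), renormalizes to `M_s`, and is accepted only if the total energy
#' does not increase (backtracking step control).  Convergence is declared
#' when the maximum per-voxel reduced torque `|m x H| / |H|` falls below
#' `tolerance`.
#'
#' @param initial a [vector_field3d] normalized inside the mask.
#' @param params a [material_params].
#' @param applied external flux density (T), length 3.
#' @param tolerance reduced-torque convergence threshold.
#' @param max_iter iteration cap; hitting it is reported in the result, not
#'   an error.
#' @param alpha0 initial dimensionless step.
#' @param plan optional precomputed demag plan.
#' @param quiet suppress the non-convergence warning.
#' @return A list with `field` (relaxed [vector_field3d]), `energy` (final
#'   breakdown), `converged`, `iterations`, `max_torque`, `energy_history`.
#' @export
minimize <- function(initial, params, applied = c(0, 0, 0),
                     tolerance = 1e-5, max_iter = 20000, alpha0 = 0.05,
                     plan = NULL, quiet = FALSE) {
  h <- initial$voxel_size
  mask <- initial$mask
  Ms <- params$M_s
  if (is.null(plan)) plan <- demag_plan(dim(initial$mx), h)
  f <- normalize_field(initial, Ms)
  ef <- effective_field(f, params, applied, plan)
  E <- ef$energy$total
  history <- E
  it <- 0L
  conv <- FALSE
  max_tau <- Inf
  idx <- which(mask)
  # dimensionless step on the reduced field h = H / Ms; adapted by a
  # Barzilai-Borwein secant estimate with an energy-decrease safeguard
  Hx <- ef$H[[1]] / Ms; Hy <- ef$H[[2]] / Ms; Hz <- ef$H[[3]] / Ms
  Hscale <- stats::median(sqrt(Hx^2 + Hy^2 + Hz^2)[idx]) + 1e-300
  s <- alpha0 / Hscale
  pm <- NULL
  while (it < max_iter) {
    it <- it + 1L
    mx <- f$mx / Ms; my <- f$my / Ms; mz <- f$mz / Ms
    Hmag <- sqrt(Hx^2 + Hy^2 + Hz^2)
    tx <- my * Hz - mz * Hy
    ty <- mz * Hx - mx * Hz
    tz <- mx * Hy - my * Hx
    max_tau <- max(sqrt(tx^2 + ty^2 + tz^2)[idx] / pmax(Hmag[idx], 1e-300))
    if (max_tau < tolerance) { conv <- TRUE; break }
    accepted <- FALSE
    stuck <- FALSE
    while (!accepted) {
      nx <- mx + s * Hx; ny <- my + s * Hy; nz <- mz + s * Hz
      nrm <- sqrt(nx^2 + ny^2 + nz^2)
      nrm[!mask | nrm == 0] <- 1
      nx <- nx / nrm; ny <- ny / nrm; nz <- nz / nrm
      nx[!mask] <- 0; ny[!mask] <- 0; nz[!mask] <- 0
      f2 <- vector_field3d(Ms * nx, Ms * ny, Ms * nz, h, mask, f$origin)
      ef2 <- effective_field(f2, params, applied, plan)
      if (ef2$energy$total <= E + abs(E) * 1e-12) {
        H2x <- ef2$H[[1]] / Ms; H2y <- ef2$H[[2]] / Ms; H2z <- ef2$H[[3]] / Ms
        # secant step from the accepted move (gradient is -H up to a
        # positive constant): s_bb = <dm, dm> / |<dm, dh>|
        dmx <- nx - mx; dmy <- ny - my; dmz <- nz - mz
        dgx <- Hx - H2x; dgy <- Hy - H2y; dgz <- Hz - H2z
        num <- sum(dmx^2 + dmy^2 + dmz^2)
        den <- abs(sum(dmx * dgx + dmy * dgy + dmz * dgz))
        f <- f2; ef <- ef2; E <- ef2$energy$total
        Hx <- H2x; Hy <- H2y; Hz <- H2z
        if (den > 0 && is.finite(num / den))
          s <- min(max(num / den, 0.01 / Hscale), 100 / Hscale)
        accepted <- TRUE
      } else {
        s <- s / 2
        if (s * Hscale < 1e-12) { accepted <- TRUE; stuck <- TRUE }
      }
    }
    history <- c(history, E)
    if (stuck) break
  }
  if (!conv && !quiet)
    warning(sprintf(
      "minimize did not reach tolerance %.1e in %d iterations (max torque %.2e)",
      tolerance, it, max_tau))
  list(field = f, energy = ef$energy, converged = conv, iterations = it,
       max_torque = max_tau, energy_history = history)
}

#' Vortex initial state
#'
#' Tangential circulation about the long (z) axis through the mask centroid
#' plus an axial cant concentrated near the axis, scaled by the signed core
#' strength, then normalized.  Mirrors the vortex initialization used to
#' seed energy minimization toward the single-vortex ground state.
#'
#' @param mask logical voxel array with `voxel_size` attribute.
#' @param M_s saturation magnetization (A/m).
#' @param core_strength signed integer; its sign sets the core polarity
#'   (+z or -z) and its magnitude the width of the axial cant, in voxels
#'   (the customary value is +/-2).
#' @param circulation +1 or -1 in-plane winding sense.
#' @return A [vector_field3d].
#' @export
vortex_initialize <- function(mask, M_s, core_strength = 2, circulation = 1) {
  if (!any(mask)) stop_invalid("mask is empty")
  h <- attr(mask, "voxel_size")
  if (is.null(h)) stop_invalid("mask must carry a voxel_size attribute")
  g <- grid_coordinates(mask)
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  cx <- mean(g$x[idx[, 1]]); cy <- mean(g$y[idx[, 2]])
  X <- array(g$x, d) - cx
  Y <- array(rep(g$y, each = d[1]), d) - cy
  w <- abs(core_strength) * h
  mx <- -circulation * Y
  my <- circulation * X
  mz <- array(sign(core_strength) * w, d)
  nrm <- sqrt(mx^2 + my^2 + mz^2)
  nrm[nrm == 0] <- 1
  vector_field3d(M_s * mx / nrm, M_s * my / nrm, M_s * mz / nrm, h, mask)
}

#' Random initial state
#'
#' Isotropically distributed unit moments inside the mask, seeded.
#'
#' @inheritParams vortex_initialize
#' @param seed integer seed.
#' @export
random_initialize <- function(mask, M_s, seed = 1) {
  if (!any(mask)) stop_invalid("mask is empty")
  h <- attr(mask, "voxel_size")
  d <- dim(mask)
  with_seed(seed, {
    n <- prod(d)
    v <- matrix(stats::rnorm(3 * n), n, 3)
    v <- v / sqrt(rowSums(v^2))
    vector_field3d(array(M_s * v[, 1], d), array(M_s * v[, 2], d),
                   array(M_s * v[, 3], d), h, mask)
  })
}

#' Uniform initial state
#' @inheritParams vortex_initialize
#' @param direction length-3 direction (normalized internally).
#' @export
uniform_initialize <- function(mask, M_s, direction = c(0, 0, 1)) {
  if (!any(mask)) stop_invalid("mask is empty")
  h <- attr(mask, "voxel_size")
  d <- dim(mask)
  u <- direction / sqrt(sum(direction^2))
  vector_field3d(array(M_s * u[1], d), array(M_s * u[2], d),
                 array(M_s * u[3], d), h, mask)
}

#' Simulated hysteresis loop
#'
#' Sweeps the applied field along `axis` from `+B_max` down to `-B_max` and
#' back, minimizing at each step from the previous state (starting
#' saturated along `+axis`).  Coercivity `B_c` is interpolated from the
#' zero crossing of the descending branch of the in-field moment;
#' `M_rs` is the descending-branch remanence at zero field.  The coercivity
#' of remanence `B_cr` is measured by the DC backfield protocol (see
#' [backfield_remanence()]) when `compute_bcr` is set.
#'
#' @param mask logical voxel array with `voxel_size` attribute.
#' @param params a [material_params].
#' @param axis field axis (unit vector).
#' @param B_max,B_step sweep amplitude and step (T), `0 < B_step <= B_max`.
#' @param tolerance,max_iter minimizer settings per field step.
#' @param compute_bcr also run the backfield protocol (adds one field sweep).
#' @param misalignment_deg small tilt of the applied field away from `axis`
#'   (degrees).  A perfectly antiparallel field exerts zero torque on a
#'   collinear state, so a gradient minimizer would ride the unstable branch
#'   forever; a ~1 degree tilt is the customary symmetry-breaking device.
#'   Moments are still measured along `axis`.
#' @return A list with `loop` (data frame: branch, B, moment along axis) and
#'   `summary` (`B_c`, `B_cr`, `M_rs`, `M_sV`, `squareness`).
#' @export
hysteresis_loop <- function(mask, params, axis = c(0, 0, 1), B_max, B_step,
                            tolerance = 1e-3, max_iter = 2000,
                            compute_bcr = FALSE, misalignment_deg = 1) {
  if (B_step <= 0) stop_invalid("B_step must be positive")
  if (B_step > B_max) stop_invalid("B_step must not exceed B_max")
  h <- attr(mask, "voxel_size")
  u <- axis / sqrt(sum(axis^2))
  uf <- .tilt_axis(u, misalignment_deg)
  plan <- demag_plan(dim(mask), h)
  state <- uniform_initialize(mask, params$M_s, u)
  fields_down <- seq(B_max, -B_max, by = -B_step)
  fields_up <- seq(-B_max, B_max, by = B_step)
  mom <- function(f) sum(net_moment(f) * u)
  run_branch <- function(state, fields, branch) {
    rows <- list()
    for (B in fields) {
      res <- minimize(state, params, applied = B * uf, tolerance = tolerance,
                      max_iter = max_iter, plan = plan, quiet = TRUE)
      state <- res$field
      rows[[length(rows) + 1]] <- data.frame(branch = branch, B = B,
                                             moment = mom(state))
    }
    list(state = state, rows = do.call(rbind, rows))
  }
  dn <- run_branch(state, fields_down, "descending")
  up <- run_branch(dn$state, fields_up, "ascending")
  loop <- rbind(dn$rows, up$rows)
  desc <- dn$rows
  B_c <- NA_real_
  cross <- which(diff(sign(desc$moment)) != 0)
  if (length(cross)) {
    i <- cross[1]
    B_c <- abs(desc$B[i] - desc$moment[i] *
                 (desc$B[i + 1] - desc$B[i]) /
                 (desc$moment[i + 1] - desc$moment[i]))
  }
  M_rs <- desc$moment[which.min(abs(desc$B))]
  M_sV <- params$M_s * sum(mask) * h^3
  B_cr <- NA_real_
  if (compute_bcr) {
    sat_rem <- minimize(
      minimize(uniform_initialize(mask, params$M_s, u), params,
               applied = B_max * uf, tolerance = tolerance,
               max_iter = max_iter, plan = plan, quiet = TRUE)$field,
      params, applied = c(0, 0, 0), tolerance = tolerance,
      max_iter = max_iter, plan = plan, quiet = TRUE)$field
    bf <- backfield_remanence(
      sat_rem, params, axis = u,
      backfields = -seq(B_step, B_max, by = B_step),
      tolerance = tolerance, max_iter = max_iter, plan = plan,
      misalignment_deg = misalignment_deg)
    B_cr <- bf$B_cr
  }
  list(loop = loop,
       summary = list(B_c = B_c, B_cr = B_cr, M_rs = M_rs, M_sV = M_sV,
                      squareness = abs(M_rs) / M_sV))
}

#' DC backfield remanence protocol
#'
#' Starting from a given (typically saturation-remanent) state, applies each
#' backfield in turn along `axis`, removes it, and records the remanent
#' moment.  `B_cr` is the interpolated backfield at which the remanence
#' crosses zero.
#'
#' @param state starting [vector_field3d] (zero-field state).
#' @param params a [material_params].
#' @param axis measurement axis (unit vector).
#' @param backfields vector of (negative) fields to apply (T).
#' @param tolerance,max_iter,plan minimizer settings.
#' @param misalignment_deg small symmetry-breaking tilt of the applied
#'   field, as in [hysteresis_loop()].
#' @return A list with `table` (data frame: B, remanence) and `B_cr` (T,
#'   positive magnitude, `NA` if no crossing).
#' @export
backfield_remanence <- function(state, params, axis = c(0, 0, 1), backfields,
                                tolerance = 1e-3, max_iter = 2000,
                                plan = NULL, misalignment_deg = 1) {
  h <- state$voxel_size
  if (is.null(plan)) plan <- demag_plan(dim(state$mx), h)
  u <- axis / sqrt(sum(axis^2))
  uf <- .tilt_axis(u, misalignment_deg)
  rows <- list()
  for (B in backfields) {
    infield <- minimize(state, params, applied = B * uf, tolerance = tolerance,
                        max_iter = max_iter, plan = plan, quiet = TRUE)
    rem <- minimize(infield$field, params, applied = c(0, 0, 0),
                    tolerance = tolerance, max_iter = max_iter, plan = plan,
                    quiet = TRUE)
    rows[[length(rows) + 1]] <-
      data.frame(B = B, remanence = sum(net_moment(rem$field) * u))
  }
  tab <- do.call(rbind, rows)
  B_cr <- NA_real_
  cr <- which(diff(sign(tab$remanence)) != 0)
  if (length(cr)) {
    i <- cr[1]
    B_cr <- abs(tab$B[i] - tab$remanence[i] *
                  (tab$B[i + 1] - tab$B[i]) /
                  (tab$remanence[i + 1] - tab$remanence[i]))
  }
  list(table = tab, B_cr = B_cr)
}

# unit vector tilted by `deg` degrees away from u, toward a fixed
# perpendicular direction (deterministic symmetry breaking)
.tilt_axis <- function(u, deg) {
  if (deg == 0) return(u)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  a <- deg * pi / 180
  cos(a) * u + sin(a) * v
}

#' Low-field susceptibility tensor diagonal
#'
#' Central-difference induced moment per unit field: the ground state is
#' re-minimized in `+/- probe_field` along each axis and the susceptibility
#' is `(m(+B) - m(-B)) / 2B` along that axis.
#'
#' @param ground_state relaxed zero-field [vector_field3d].
#' @param params a [material_params].
#' @param probe_field probe amplitude (T), default 1 mT.
#' @param tolerance,max_iter minimizer settings.
#' @return Named numeric vector `c(x =, y =, z =)` in A m^2 / T.
#' @export
susceptibility <- function(ground_state, params, probe_field = 1e-3,
                           tolerance = 1e-3, max_iter = 2000) {
  plan <- demag_plan(dim(ground_state$mx), ground_state$voxel_size)
  chi <- numeric(3)
  for (i in 1:3) {
    u <- c(0, 0, 0); u[i] <- 1
    mp <- minimize(ground_state, params, applied = probe_field * u,
                   tolerance = tolerance, max_iter = max_iter, plan = plan,
                   quiet = TRUE)
    mm <- minimize(ground_state, params, applied = -probe_field * u,
                   tolerance = tolerance, max_iter = max_iter, plan = plan,
                   quiet = TRUE)
    chi[i] <- (net_moment(mp$field)[i] - net_moment(mm$field)[i]) /
      (2 * probe_field)
  }
  names(chi) <- c("x", "y", "z")
  chi
}

#' Particle growth simulation
#'
#' Grows the particle slab by slab along `z` (from the base up or the tip
#' down), randomly initializing each newly added slab and re-minimizing the
#' whole body after every addition.  The observed outcome for the spearhead
#' is that both growth directions find the same single-vortex state.
#'
#' @param mask full-particle logical voxel array with `voxel_size`.
#' @param params a [material_params].
#' @param direction `"base-up"` or `"tip-down"`.
#' @param slab_thickness slab height (m); must be an integer multiple of the
#'   voxel size.
#' @param seed integer seed for the random slab initializations.
#' @param tolerance,max_iter minimizer settings per step.
#' @param keep_history return every intermediate state (memory permitting).
#' @return A list with `final` (relaxed [vector_field3d]), `energy` (final
#'   breakdown) and, if requested, `history` (list of intermediate states).
#' @export
growth_simulation <- function(mask, params, direction = c("base-up", "tip-down"),
                              slab_thickness, seed = 1,
                              tolerance = 1e-3, max_iter = 2000,
                              keep_history = FALSE) {
  direction <- match.arg(direction)
  h <- attr(mask, "voxel_size")
  nsl <- slab_thickness / h
  if (abs(nsl - round(nsl)) > 1e-9)
    stop_invalid("slab_thickness must be a multiple of voxel_size")
  nsl <- as.integer(round(nsl))
  d <- dim(mask)
  occ <- which(apply(mask, 3, any))
  slabs <- split(occ, ceiling(seq_along(occ) / nsl))
  if (direction == "tip-down") slabs <- rev(slabs)
  plan <- demag_plan(d, h)
  Ms <- params$M_s
  cur_mask <- array(FALSE, d)
  attr(cur_mask, "voxel_size") <- h
  attr(cur_mask, "origin") <- attr(mask, "origin")
  state <- NULL
  history <- list()
  step_seed <- with_seed(seed, sample.int(2^31 - 2, length(slabs)))
  for (s in seq_along(slabs)) {
    new_mask <- cur_mask
    new_mask[, , slabs[[s]]] <- mask[, , slabs[[s]]]
    attr(new_mask, "voxel_size") <- h
    attr(new_mask, "origin") <- attr(mask, "origin")
    rnd <- random_initialize(new_mask, Ms, seed = step_seed[s])
    if (!is.null(state)) {
      keep <- cur_mask
      rnd$mx[keep] <- state$mx[keep]
      rnd$my[keep] <- state$my[keep]
      rnd$mz[keep] <- state$mz[keep]
    }
    init <- vector_field3d(rnd$mx, rnd$my, rnd$mz, h, new_mask)
    res <- minimize(init, params, tolerance = tolerance, max_iter = max_iter,
                    plan = plan, quiet = TRUE)
    state <- res$field
    cur_mask <- new_mask
    if (keep_history) history[[s]] <- state
  }
  out <- list(final = state, energy = res$energy)
  if (keep_history) out$history <- history
  out
}
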