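#' In-plane winding number around a closed pixel loop
#'
#' Accumulates the wrapped change of the in-plane magnetization angle
#' `atan2(M_y, M_x)` around a closed loop of pixels in one z-slice and
#' divides by 2 pi.  The result is the integer topological charge of the
#' in-plane texture enclosed by the loop; it is invariant to loop
#' deformation while the loop stays inside the mask and does not cross the
#' core.
#'
#' @param field a [vector_field3d].
#' @param z_slice slice index (third array dimension).
#' @param loop integer matrix with columns (i, j) of pixel indices tracing a
#'   closed loop (the closing edge from last to first point is implied).
#' @param min_inplane smallest in-plane magnitude (relative to the slice
#'   maximum) accepted on the loop before the loop is declared degenerate.
#' @return Integer winding number.
#' @export
winding_number <- function(field, z_slice, loop, min_inplane = 1e-6) {
  mx <- field$mx[, , z_slice]
  my <- field$my[, , z_slice]
  idx <- cbind(loop[, 1], loop[, 2])
  vx <- mx[idx]; vy <- my[idx]
  ip <- sqrt(vx^2 + vy^2)
  if (any(ip < min_inplane * max(sqrt(mx^2 + my^2))))
    stop_invalid("degenerate loop: in-plane magnetization vanishes on the loop")
  if (any(!field$mask[, , z_slice][idx]))
    stop_invalid("loop leaves the mask")
  th <- atan2(vy, vx)
  dth <- diff(c(th, th[1]))
  dth <- (dth + pi) %% (2 * pi) - pi
  as.integer(round(sum(dth) / (2 * pi)))
}

#' Rectangular loop helper
#'
#' Builds a closed rectangular pixel loop centered on `(i, j)` with
#' half-width `r`, for use with [winding_number()].
#'
#' @param i,j center pixel indices.
#' @param r half-width in pixels.
#' @return Integer matrix of loop pixels in order.
#' @export
rectangle_loop <- function(i, j, r) {
  top <- cbind(seq(i - r, i + r), j - r)
  right <- cbind(i + r, seq(j - r + 1, j + r))
  bottom <- cbind(seq(i + r - 1, i - r), j + r)
  left <- cbind(i - r, seq(j + r - 1, j - r + 1))
  rbind(top, right, bottom, left)
}

# Per-slice plaquette winding: w[i,j] is the winding of the in-plane angle
# around the unit cell with corners (i,j),(i+1,j),(i+1,j+1),(i,j+1).
.plaquette_winding <- function(mx, my) {
  th <- atan2(my, mx)
  d <- dim(th)
  wrap <- function(x) (x + pi) %% (2 * pi) - pi
  a <- th[-d[1], -d[2]]   # (i, j)
  b <- th[-1, -d[2]]      # (i+1, j)
  cc <- th[-1, -1]        # (i+1, j+1)
  dd <- th[-d[1], -1]     # (i, j+1)
  (wrap(b - a) + wrap(cc - b) + wrap(dd - cc) + wrap(a - dd)) / (2 * pi)
}

#' Trace the vortex core through a vector field
#'
#' For every occupied z-slice the in-plane winding singularity is located:
#' plaquette winding numbers identify the cell carrying unit topological
#' charge, and the core is refined to subpixel precision by a quadratic fit
#' of the in-plane magnetization magnitude around its local minimum.  Cores
#' are linked across slices by nearest neighbor (ties and multiple
#' candidates resolve to the candidate closest to the previous slice's
#' core).  The polarization at each point is the sign of the interpolated
#' M_z on the core; positions where it changes sign are reported as Bloch
#' points.
#'
#' @param field a [vector_field3d].
#' @param min_fill smallest fraction of mask voxels a slice needs before it
#'   is searched (suppresses end caps a voxel wide).
#' @return An object of class `core_path`: a list with `points` (data frame
#'   z, x, y in meters plus slice index), `polarization` (+/-1 per point),
#'   `mz` (interpolated M_z on the core), `bloch_points` (matrix of
#'   crossing positions, possibly empty), `circulation` (+/-1) and
#'   `broken_slices` (indices of interior slices with no singularity).
#' @export
trace_core <- function(field, min_fill = 0.002) {
  d <- dim(field$mx)
  h <- field$voxel_size
  g <- grid_coordinates(field$mask)
  occ <- apply(field$mask, 3, sum)
  total <- sum(occ)
  slices <- which(occ > pmax(4, min_fill * max(occ)))
  pts <- list()
  broken <- integer(0)
  prev <- NULL
  circ <- integer(0)
  for (k in slices) {
    mx <- field$mx[, , k]; my <- field$my[, , k]
    mk <- field$mask[, , k]
    w <- .plaquette_winding(mx, my)
    # only cells whose 4 corners are inside the mask are trustworthy
    mk4 <- mk[-d[1], -d[2]] & mk[-1, -d[2]] & mk[-1, -1] & mk[-d[1], -1]
    cand <- which(abs(w) > 0.5 & mk4, arr.ind = TRUE)
    if (nrow(cand) == 0) { broken <- c(broken, k); prev <- NULL; next }
    if (nrow(cand) > 1) {
      if (!is.null(prev)) {
        dist <- (cand[, 1] - prev[1])^2 + (cand[, 2] - prev[2])^2
        cand <- cand[which.min(dist), , drop = FALSE]
      } else {
        ip <- sqrt(mx^2 + my^2)
        ipc <- ip[cbind(cand[, 1], cand[, 2])]
        cand <- cand[which.min(ipc), , drop = FALSE]
      }
    }
    ci <- cand[1, 1]; cj <- cand[1, 2]
    # circulation = chirality (sense of rotation about the core), the sign
    # of the discrete curl; distinct from the winding number, whose degree
    # is +1 for a vortex of either sense
    i0 <- max(2, min(ci, d[1] - 1)); j0 <- max(2, min(cj, d[2] - 1))
    curlz <- (my[i0 + 1, j0] - my[i0 - 1, j0]) -
      (mx[i0, j0 + 1] - mx[i0, j0 - 1])
    circ <- c(circ, sign(curlz))
    # subpixel: quadratic fit of in-plane magnitude^2 on the 3x3 block
    # around the integer minimum near the singular cell
    ip2 <- mx^2 + my^2
    block_i <- max(2, min(ci, d[1] - 1))
    block_j <- max(2, min(cj, d[2] - 1))
    # integer minimum among the 4 cell corners
    corners <- rbind(c(ci, cj), c(ci + 1, cj), c(ci, cj + 1), c(ci + 1, cj + 1))
    vals <- ip2[corners]
    m0 <- corners[which.min(vals), ]
    i0 <- max(2, min(m0[1], d[1] - 1))
    j0 <- max(2, min(m0[2], d[2] - 1))
    sub <- .quad_min_2d(ip2[(i0 - 1):(i0 + 1), (j0 - 1):(j0 + 1)])
    pos_i <- i0 + sub[1]
    pos_j <- j0 + sub[2]
    mzc <- .bilinear_at(field$mz[, , k], pos_i, pos_j)
    pts[[length(pts) + 1]] <- c(k, pos_i, pos_j, mzc)
    prev <- c(pos_i, pos_j)
  }
  if (length(pts) == 0) stop_invalid("no vortex core found in any slice")
  P <- do.call(rbind, pts)
  # interior gaps are diagnostics; gaps at the ends are just the caps
  if (length(broken)) {
    interior <- broken[broken > min(P[, 1]) & broken < max(P[, 1])]
    if (length(interior))
      warning(sprintf("broken core: no singularity in interior slice(s) %s",
                      paste(interior, collapse = ", ")))
    broken <- interior
  }
  pol <- sign(P[, 4])
  pol[pol == 0] <- 1
  # Bloch points at sustained polarization sign changes.  The raw sign of
  # the core M_z is noisy where the core moment passes through zero, and
  # the particle end caps flip M_z spuriously on coarse grids (closure
  # fields), so: (i) the sign sequence is median-filtered over 3 slices,
  # (ii) the first and last traced slices are excluded, and (iii) a change
  # only counts when the polarity is strong (relative to the path median)
  # within a few slices on both sides.
  bp <- NULL
  np <- nrow(P)
  mz_scale <- stats::median(abs(P[, 4]))
  pol_f <- if (np >= 3) sign(stats::runmed(P[, 4], 3)) else pol
  pol_f[pol_f == 0] <- 1
  ch <- which(diff(pol_f) != 0)
  ch <- ch[ch > 1 & ch + 1 < np]
  sustained <- vapply(ch, function(i) {
    lo <- max(1, i - 3):i
    hi <- (i + 1):min(np, i + 4)
    max(abs(P[lo, 4])) >= 0.2 * mz_scale &&
      max(abs(P[hi, 4])) >= 0.2 * mz_scale
  }, logical(1))
  ch <- ch[sustained]
  for (i in ch) {
    z1 <- g$z[P[i, 1]]; z2 <- g$z[P[i + 1, 1]]
    f <- if (P[i, 4] != P[i + 1, 4])
      P[i, 4] / (P[i, 4] - P[i + 1, 4]) else 0.5
    bp <- rbind(bp, c(
      x = (1 - f) * .idx_to_pos(P[i, 2], g$x) + f * .idx_to_pos(P[i + 1, 2], g$x),
      y = (1 - f) * .idx_to_pos(P[i, 3], g$y) + f * .idx_to_pos(P[i + 1, 3], g$y),
      z = (1 - f) * z1 + f * z2))
  }
  structure(list(
    points = data.frame(slice = P[, 1],
                        z = g$z[P[, 1]],
                        x = .idx_to_pos(P[, 2], g$x),
                        y = .idx_to_pos(P[, 3], g$y)),
    polarization = pol_f,
    mz = P[, 4],
    bloch_points = bp,
    circulation = as.integer(sign(sum(circ))),
    broken_slices = broken,
    voxel_size = h), class = "core_path")
}

#' @export
print.core_path <- function(x, ...) {
  cat(sprintf(
    "core_path: %d points, circulation %+d, %d Bloch point(s)\n",
    nrow(x$points), x$circulation,
    if (is.null(x$bloch_points)) 0L else nrow(x$bloch_points)))
  invisible(x)
}

# fractional index -> physical coordinate along an axis vector
.idx_to_pos <- function(i, axis) axis[1] + (i - 1) * (axis[2] - axis[1])

# bilinear interpolation of a matrix at fractional indices
.bilinear_at <- function(M, i, j) {
  d <- dim(M)
  i <- min(max(i, 1), d[1]); j <- min(max(j, 1), d[2])
  i0 <- min(floor(i), d[1] - 1); j0 <- min(floor(j), d[2] - 1)
  fi <- i - i0; fj <- j - j0
  (1 - fi) * (1 - fj) * M[i0, j0] + fi * (1 - fj) * M[i0 + 1, j0] +
    (1 - fi) * fj * M[i0, j0 + 1] + fi * fj * M[i0 + 1, j0 + 1]
}

# subpixel minimum of a 3x3 patch by separable quadratic fit, clamped to
# half a pixel
.quad_min_2d <- function(patch) {
  off <- function(a, b, c) {
    den <- a - 2 * b + c
    if (den <= 0) return(0)
    max(min(0.5 * (a - c) / den, 0.5), -0.5)
  }
  c(off(patch[1, 2], patch[2, 2], patch[3, 2]),
    off(patch[2, 1], patch[2, 2], patch[2, 3]))
}

#' Detect Bloch points on a traced core
#'
#' For every polarization sign change along the core, reports the crossing
#' position and the minimum magnetization magnitude within a 3-voxel
#' neighborhood.  At a Bloch point the magnetization magnitude is locally
#' depressed (it vanishes at the singularity in the continuum picture), so
#' the report includes `min_magnitude` relative to the field's typical
#' inside-mask magnitude.
#'
#' @param core a [trace_core()] result.
#' @param field the [vector_field3d] the core was traced from.
#' @return A data frame with columns x, y, z (m), `min_magnitude` (A/m) and
#'   `relative_magnitude`; zero rows when the core has constant
#'   polarization.
#' @export
detect_bloch_points <- function(core, field) {
  if (is.null(core$bloch_points))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      min_magnitude = numeric(0),
                      relative_magnitude = numeric(0)))
  g <- grid_coordinates(field$mask)
  mag <- field_magnitude(field)
  ms <- stats::median(mag[field$mask])
  out <- NULL
  for (r in seq_len(nrow(core$bloch_points))) {
    p <- core$bloch_points[r, ]
    i <- round((p["x"] - g$x[1]) / field$voxel_size) + 1
    j <- round((p["y"] - g$y[1]) / field$voxel_size) + 1
    k <- round((p["z"] - g$z[1]) / field$voxel_size) + 1
    d <- dim(mag)
    ii <- max(1, i - 1):min(d[1], i + 1)
    jj <- max(1, j - 1):min(d[2], j + 1)
    kk <- max(1, k - 1):min(d[3], k + 1)
    nb <- mag[ii, jj, kk]
    nb <- nb[field$mask[ii, jj, kk]]
    mn <- if (length(nb)) min(nb) else NA_real_
    out <- rbind(out, data.frame(x = p[["x"]], y = p[["y"]], z = p[["z"]],
                                 min_magnitude = mn,
                                 relative_magnitude = mn / ms))
  }
  rownames(out) <- NULL
  out
}

#' Extract the medial domain wall (M_z = 0 surface) and its twist
#'
#' Finds the zero level set of M_z inside the particle, slice by slice,
#' using contour extraction, and measures the in-plane orientation of the
#' wall trace in every slice (angle of the principal axis of the contour
#' points, unwrapped along z).  A tip twist is flagged when the unwrapped
#' orientation rotates by more than `twist_threshold` over the tip region
#' relative to the body.
#'
#' @param field a [vector_field3d] whose mask contains both M_z signs.
#' @param erode keep only wall vertices at least this many voxels inside the
#'   mask edge (suppresses spurious boundary contours).
#' @param tip_fraction fraction of the occupied length counted as the tip.
#' @param twist_threshold rotation (degrees) that raises the twist flag.
#' @return An object of class `medial_wall`: `vertices` (data frame x, y, z
#'   in meters, plus slice), `twist_profile` (data frame z, angle_deg,
#'   unwrapped), `twist_flag`, `twist_range` (degrees).
#' @export
extract_medial_wall <- function(field, erode = 1L, tip_fraction = 0.3,
                                twist_threshold = 45) {
  d <- dim(field$mz)
  mzin <- field$mz[field$mask]
  if (all(mzin >= 0) || all(mzin <= 0))
    stop_invalid("no medial wall: M_z does not change sign inside the mask")
  ms <- max(abs(mzin))
  g <- grid_coordinates(field$mask)
  verts <- list()
  prof <- list()
  for (k in seq_len(d[3])) {
    mk <- field$mask[, , k]
    if (sum(mk) < 9) next
    mz <- field$mz[, , k]
    if (all(mz[mk] >= 0) || all(mz[mk] <= 0)) next
    # fill outside-mask with the sign-preserving plateau so the only zero
    # contour inside the eroded mask is the wall itself
    fill <- ifelse(mz == 0 & !mk, ms, mz)
    cl <- grDevices::contourLines(g$x, g$y, fill, levels = 0)
    if (!length(cl)) next
    er <- .erode_mask2d(mk, erode)
    px <- c(); py <- c()
    for (seg in cl) {
      ii <- round((seg$x - g$x[1]) / field$voxel_size) + 1
      jj <- round((seg$y - g$y[1]) / field$voxel_size) + 1
      keep <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
      keep[keep] <- er[cbind(ii[keep], jj[keep])]
      px <- c(px, seg$x[keep]); py <- c(py, seg$y[keep])
    }
    if (length(px) < 3) next
    verts[[length(verts) + 1]] <-
      data.frame(x = px, y = py, z = g$z[k], slice = k)
    # principal-axis angle of the wall trace (orientation mod 180 deg)
    cx <- px - mean(px); cy <- py - mean(py)
    cm <- cbind(cx, cy)
    ev <- eigen(crossprod(cm), symmetric = TRUE)$vectors[, 1]
    ang <- atan2(ev[2], ev[1]) * 180 / pi
    prof[[length(prof) + 1]] <- c(z = g$z[k], angle = ang %% 180, slice = k)
  }
  if (!length(verts))
    stop_invalid("no medial wall: M_z zero crossing not resolved in any slice")
  vertices <- do.call(rbind, verts)
  pr <- as.data.frame(do.call(rbind, prof))
  # unwrap orientation (period 180 deg) along z
  unw <- pr$angle
  for (i in seq_len(nrow(pr))[-1]) {
    delta <- unw[i] - unw[i - 1]
    unw[i] <- unw[i] - 180 * round(delta / 180)
  }
  pr$unwrapped <- unw
  nb <- nrow(pr)
  body_idx <- seq_len(max(1, floor((1 - tip_fraction) * nb)))
  tip_idx <- setdiff(seq_len(nb), body_idx)
  body_ang <- stats::median(unw[body_idx])
  twist_range <- if (length(tip_idx))
    max(abs(unw[tip_idx] - body_ang)) else 0
  structure(list(vertices = vertices,
                 twist_profile = pr[, c("z", "angle", "unwrapped")],
                 twist_flag = twist_range > twist_threshold,
                 twist_range = twist_range), class = "medial_wall")
}

#' @export
print.medial_wall <- function(x, ...) {
  cat(sprintf(
    "medial_wall: %d vertices over %d slices, twist range %.1f deg%s\n",
    nrow(x$vertices), length(unique(x$vertices$slice)), x$twist_range,
    if (x$twist_flag) " (tip twist flagged)" else ""))
  invisible(x)
}

.erode_mask2d <- function(m, n) {
  if (n <= 0) return(m)
  for (r in seq_len(n)) {
    d <- dim(m)
    e <- m
    e[-1, ] <- e[-1, ] & m[-d[1], ]
    e[-d[1], ] <- e[-d[1], ] & m[-1, ]
    e[, -1] <- e[, -1] & m[, -d[2]]
    e[, -d[2]] <- e[, -d[2]] & m[, -1]
    m <- e
  }
  m
}
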