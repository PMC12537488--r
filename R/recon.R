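#' Align a tilt series
#'
#' Registration in two stages, mirroring standard tomographic practice:
#' first each image is registered to its angular neighbor by the integer
#' peak of the FFT cross-correlation (using the charge images when present,
#' since they are noise-robust and angle-stable), then the vertical offsets
#' are refined to subpixel precision by aligning the center of mass of the
#' charge image along the tilt-axis-parallel direction (the projected mass
#' profile along the tilt axis is invariant under tilt).
#'
#' @param series a [tilt_series] with at least 2 images.
#' @return The series with aligned images (and charge images), plus a
#'   `recovered_shifts` field (n x 2, pixels) estimating the shift that had
#'   been applied to each raw image.
#' @export
align_series <- function(series) {
  n <- length(series$images)
  if (n < 2) stop_invalid("series must contain at least 2 images")
  refs <- if (!is.null(series$charge_images)) series$charge_images
          else series$images
  if (all(vapply(refs, function(i) stats::sd(i) == 0, logical(1))))
    stop_invalid("alignment failure: images are featureless (constant)")
  d <- dim(refs[[1]])
  rec <- matrix(0, n, 2)
  # anchor on the image nearest 0 degrees, walk outwards
  anchor <- which.min(abs(series$angles))
  order_out <- order(abs(seq_len(n) - anchor))
  aligned_ref <- refs
  for (i in order_out) {
    if (i == anchor) next
    j <- if (i > anchor) i - 1L else i + 1L
    s <- .xcorr_peak(aligned_ref[[j]], refs[[i]])
    rec[i, ] <- s
    aligned_ref[[i]] <- .shift_image(refs[[i]], -s[1], -s[2])
  }
  # subpixel vertical mass alignment on the charge signal
  prof_com <- function(I) {
    p <- rowSums(pmax(I, 0))
    if (sum(p) <= 0) return(NA_real_)
    sum(seq_along(p) * p) / sum(p)
  }
  coms <- vapply(aligned_ref, prof_com, numeric(1))
  target <- stats::median(coms, na.rm = TRUE)
  dv <- ifelse(is.na(coms), 0, coms - target)
  rec[, 1] <- rec[, 1] + dv
  images <- vector("list", n)
  charges <- if (!is.null(series$charge_images)) vector("list", n) else NULL
  for (i in seq_len(n)) {
    images[[i]] <- .shift_image(series$images[[i]], -rec[i, 1], -rec[i, 2])
    if (!is.null(charges))
      charges[[i]] <- .shift_image(series$charge_images[[i]], -rec[i, 1], -rec[i, 2])
  }
  out <- tilt_series(images, series$angles, series$axis_id,
                     series$pixel_size, applied_shifts = series$applied_shifts,
                     charge_images = charges, volume_dim = series$volume_dim)
  out$recovered_shifts <- rec
  out
}

# Integer shift of B relative to A by FFT cross-correlation peak:
# returns s such that shifting B by -s best matches A.
.xcorr_peak <- function(A, B) {
  d <- dim(A)
  FA <- stats::fft(A - mean(A))
  FB <- stats::fft(B - mean(B))
  cc <- Re(stats::fft(FA * Conj(FB), inverse = TRUE))
  k <- which.max(cc)
  i <- (k - 1) %% d[1]
  j <- (k - 1) %/% d[1]
  if (i > d[1] / 2) i <- i - d[1]
  if (j > d[2] / 2) j <- j - d[2]
  c(-i, -j)
}

#' Register the two tilt-series frames
#'
#' Aligns the second series' frame to the first by cross-correlating the
#' images nearest zero tilt after rotating the second by 90 degrees
#' in-plane.  Both rotation senses are tried and the one with the higher
#' correlation peak is kept, disambiguating the sign of the 90-degree
#' in-plane rotation between the two acquisitions.  The magnetic (XMCD)
#' images are used for the correlation: the charge image of a near-axially
#' symmetric particle is mirror symmetric and cannot distinguish the two
#' senses, while the antisymmetric magnetic contrast can.
#'
#' @param series1,series2 [tilt_series] objects; each must contain an image
#'   within `max_angle` of zero tilt.
#' @param max_angle largest |angle| (degrees) accepted as the zero-tilt
#'   reference.
#' @return A list with `offset` (length-2, pixels, applying to series2 after
#'   rotation), `rotation_sense` (+1 or -1), and `peak_correlations` for the
#'   two senses.
#' @export
register_axes <- function(series1, series2, max_angle = 2) {
  i1 <- which.min(abs(series1$angles))
  i2 <- which.min(abs(series2$angles))
  if (abs(series1$angles[i1]) > max_angle || abs(series2$angles[i2]) > max_angle)
    stop_invalid("both series must contain a near-zero-angle projection")
  A <- series1$images[[i1]]
  B <- series2$images[[i2]]
  rot_p <- t(B)[, rev(seq_len(nrow(B))), drop = FALSE]   # +90 in-plane
  rot_m <- t(B)[rev(seq_len(ncol(B))), , drop = FALSE]   # -90 in-plane
  score <- function(Bp) {
    if (!identical(dim(Bp), dim(A))) return(list(peak = -Inf, s = c(0, 0)))
    FA <- stats::fft(A - mean(A)); FB <- stats::fft(Bp - mean(Bp))
    cc <- Re(stats::fft(FA * Conj(FB), inverse = TRUE))
    k <- which.max(cc)
    d <- dim(A)
    i <- (k - 1) %% d[1]; j <- (k - 1) %/% d[1]
    if (i > d[1] / 2) i <- i - d[1]
    if (j > d[2] / 2) j <- j - d[2]
    list(peak = max(cc) / (stats::sd(A) * stats::sd(Bp) * length(A)),
         s = c(-i, -j))
  }
  sp <- score(rot_p); sm <- score(rot_m)
  if (sp$peak >= sm$peak)
    list(offset = sp$s, rotation_sense = 1L,
         peak_correlations = c(plus = sp$peak, minus = sm$peak))
  else
    list(offset = sm$s, rotation_sense = -1L,
         peak_correlations = c(plus = sp$peak, minus = sm$peak))
}

# Forward projection of component volumes through one series' geometry.
# Returns list of model images.  `vols` are in the series' own (possibly
# pre-rotated) frame.
.series_forward <- function(vols, geoms, beams, h) {
  n <- length(geoms)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    b <- beams[[i]]
    img <- 0
    for (c in 1:3) if (b[c] != 0)
      img <- img + b[c] * .project_scalar_tilt(vols[[c]], geoms[[i]])
    out[[i]] <- img * h
  }
  out
}

# Adjoint: accumulates the back-projection of residual images into component
# volumes (series frame).
.series_backward <- function(resids, geoms, beams, d, h) {
  g <- list(array(0, d), array(0, d), array(0, d))
  for (i in seq_along(resids)) {
    bp <- .backproject_scalar_tilt(resids[[i]], geoms[[i]], d)
    b <- beams[[i]]
    for (c in 1:3) if (b[c] != 0) g[[c]] <- g[[c]] + (b[c] * h) * bp
  }
  g
}

#' Gradient-based iterative vector tomography reconstruction
#'
#' Reconstructs the 3D magnetization vector field from two aligned tilt
#' series about perpendicular rotation axes.  Starting from a zero-filled
#' object, each iteration forward-projects the current guess at every
#' measured angle of both series, forms the sum-squared-difference error
#' against the measured images, updates all three components along the
#' negative gradient (back-projection of the residuals weighted by the
#' per-angle beam-direction components) with an exact line-search step (the
#' objective is quadratic in the step), and re-applies the particle mask.
#' The error is non-increasing by construction.
#'
#' @param series1,series2 aligned [tilt_series] for the first and second
#'   rotation axes (`axis_id` must be `"first"` and `"second"`).
#' @param mask logical voxel array (reconstruction support) with
#'   `voxel_size` attribute matching the series' pixel size.
#' @param n_iterations number of iterations (default 10).
#' @param scale XMCD signal scale used in the forward model.
#' @return A list with `field` (a [vector_field3d], A/m in signal-consistent
#'   units), `error_history` (sum-squared error after each iteration,
#'   preceded by the zero-object error), and `iteration_count`.
#' @export
reconstruct_vector <- function(series1, series2, mask, n_iterations = 10,
                               scale = 1) {
  if (series1$axis_id != "first" || series2$axis_id != "second")
    stop_invalid("series1 must be the first-axis series and series2 the second")
  d <- dim(mask)
  h <- attr(mask, "voxel_size")
  if (is.null(h)) h <- series1$pixel_size
  d1 <- dim(series1$images[[1]])
  if (!identical(as.integer(d1), as.integer(c(d[2], d[3]))))
    stop_invalid("series1 image dimensions do not match the mask grid")
  d2img <- dim(series2$images[[1]])
  if (!identical(as.integer(d2img), as.integer(c(d[3], d[2]))))
    stop_invalid("series2 image dimensions do not match the mask grid")
  hh <- h * scale
  geoms1 <- lapply(series1$angles, function(a) .tilt_geometry(d[1], d[3], a))
  beams1 <- lapply(series1$angles, .beam_direction, axis_id = "first")
  drot <- c(d[1], d[3], d[2])
  geoms2 <- lapply(series2$angles, function(a) .tilt_geometry(drot[1], drot[3], a))
  beams2 <- lapply(series2$angles, .beam_direction, axis_id = "second")
  maskn <- array(as.numeric(mask), d)

  m <- list(array(0, d), array(0, d), array(0, d))
  sse <- function(r) sum(vapply(r, function(x) sum(x^2), numeric(1)))
  forward_all <- function(vols) {
    vrot <- lapply(vols, .rot90_vol)
    list(s1 = .series_forward(vols, geoms1, beams1, hh),
         s2 = .series_forward(vrot, geoms2, beams2, hh))
  }
  resid <- function(mod)
    list(s1 = mapply(function(a, b) a - b, mod$s1, series1$images,
                     SIMPLIFY = FALSE),
         s2 = mapply(function(a, b) a - b, mod$s2, series2$images,
                     SIMPLIFY = FALSE))
  mod <- forward_all(m)
  r <- resid(mod)
  err <- sse(r$s1) + sse(r$s2)
  history <- err
  for (it in seq_len(n_iterations)) {
    g1 <- .series_backward(r$s1, geoms1, beams1, d, hh)
    g2rot <- .series_backward(r$s2, geoms2, beams2, drot, hh)
    g <- mapply(function(a, b) (a + .rot90_vol_inv(b)) * maskn, g1, g2rot,
                SIMPLIFY = FALSE)
    gg <- sum(vapply(g, function(x) sum(x^2), numeric(1)))
    if (gg == 0) break
    pd <- forward_all(g)                     # projection of the direction
    denom <- sse(pd$s1) + sse(pd$s2)
    if (denom == 0) break
    alpha <- gg / denom
    m <- mapply(function(a, b) a - alpha * b, m, g, SIMPLIFY = FALSE)
    mod$s1 <- mapply(function(a, b) a - alpha * b, mod$s1, pd$s1,
                     SIMPLIFY = FALSE)
    mod$s2 <- mapply(function(a, b) a - alpha * b, mod$s2, pd$s2,
                     SIMPLIFY = FALSE)
    r <- resid(mod)
    err <- sse(r$s1) + sse(r$s2)
    history <- c(history, err)
  }
  field <- vector_field3d(m[[1]], m[[2]], m[[3]], h, mask)
  list(field = field, error_history = history,
       iteration_count = length(history) - 1L)
}
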