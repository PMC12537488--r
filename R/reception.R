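#' Ratio of magnetic to thermal energy
#'
#' `MB / k_B T` for a magnetic moment in an external field: the figure of
#' merit for both magnetotaxis and torque-based magnetoreception.
#'
#' @param moment magnetic moment (A m^2), non-negative.
#' @param field flux density (T), non-negative.
#' @param temperature absolute temperature (K), positive.
#' @return Dimensionless energy in units of `k_B T`.
#' @examples
#' mb_ratio(1e-14, 50e-6, 298)   # ~121 for the giant spearhead
#' mb_ratio(5e-16, 50e-6, 298)   # ~6 for a trout-type nanoparticle cluster
#' @export
mb_ratio <- function(moment, field, temperature) {
  if (any(moment < 0)) stop_invalid("moment must be non-negative")
  if (any(field < 0)) stop_invalid("field must be non-negative")
  if (any(temperature <= 0)) stop_invalid("temperature must be positive")
  moment * field / (.kB * temperature)
}

#' Moment of a uniformly magnetized cylindrical needle
#'
#' @param diameter,length cylinder dimensions (m), positive (zero length
#'   gives zero moment).
#' @param M_s saturation magnetization (A/m); defaults to magnetite.
#' @return Moment (A m^2): `M_s * pi * (d/2)^2 * L`.
#' @examples
#' needle_moment(100e-9, 2e-6)   # ~7.55e-15 A m^2
#' @export
needle_moment <- function(diameter, length, M_s = 4.80768e5) {
  if (any(diameter <= 0)) stop_invalid("diameter must be positive")
  if (any(length < 0)) stop_invalid("length must be non-negative")
  M_s * pi * (diameter / 2)^2 * length
}

# Boltzmann moments of the deflection angle psi on (-pi, pi] for the
# torque-transducer energy u(psi) = -MB cos(theta - psi) + K psi^2 / 2
# (thermal units).  Integrands are shifted by the minimum energy for
# numerical stability; adaptive quadrature to rel.tol.
.psi_moments <- function(MB, K, theta, rel.tol = 1e-10) {
  u <- function(psi) -MB * cos(theta - psi) + 0.5 * K * psi^2
  u0 <- stats::optimize(u, c(-pi, pi))$objective
  f <- function(p, pow) p^pow * exp(-(u(p) - u0))
  Z <- stats::integrate(f, -pi, pi, pow = 0, rel.tol = rel.tol,
                        subdivisions = 400L)$value
  m1 <- stats::integrate(f, -pi, pi, pow = 1, rel.tol = rel.tol,
                         subdivisions = 400L)$value / Z
  m2 <- stats::integrate(f, -pi, pi, pow = 2, rel.tol = rel.tol,
                         subdivisions = 400L)$value / Z
  list(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

#' Boltzmann deflection statistics of the torque transducer
#'
#' An elastically anchored magnetic particle with magnetic energy `MB` and
#' torsional stiffness `K` (both in units of `k_B T`) in a field applied at
#' angle `theta` to its rest position has deflection energy
#' `u(psi) = -MB cos(theta - psi) + K psi^2 / 2`.  The deflection angle is
#' Boltzmann-distributed, `p(psi) ~ exp(-u(psi))` on `(-pi, pi]`; this
#' returns its mean and standard deviation (the thermal fluctuation
#' amplitude) by adaptive quadrature.
#'
#' @param MB magnetic energy (k_B T units), >= 0.
#' @param K torsional stiffness (k_B T units), > 0; the elastic energy is
#'   `K psi^2 / 2`.
#' @param theta field angle to the rest position (degrees); 180 is the
#'   antiparallel configuration at which the critical point occurs.
#' @param rel.tol quadrature relative tolerance.
#' @return A list with `mean_psi` and `delta_psi` (radians).
#' @examples
#' deflection_statistics(121, 121, 180)  # at the critical point MB/K = 1
#' @export
deflection_statistics <- function(MB, K, theta = 180, rel.tol = 1e-10) {
  if (MB < 0) stop_invalid("MB must be non-negative")
  if (K <= 0) stop_invalid("K must be positive")
  m <- .psi_moments(MB, K, theta * pi / 180, rel.tol)
  list(mean_psi = m$mean, delta_psi = m$sd)
}

#' Fluctuation-amplitude sensitivity curve at the critical point
#'
#' Computes the fluctuation amplitude `delta_psi` as a function of the ratio
#' `MB/K` for a field antiparallel to the rest position, and its derivative
#' `d(delta_psi)/d(MB/K)` (the sharpness of the field response).  Near
#' `MB/K = 1` the system passes a critical point where the amplitude rises
#' most rapidly with field intensity.  Both the derivative at exactly
#' `MB/K = 1` (the critical point) and the maximum of the derivative over
#' the grid (with its location, slightly above 1 at finite `K`) are
#' reported.
#'
#' @param K torsional stiffness (k_B T units).
#' @param theta field angle (degrees), default 180.
#' @param ratio_grid grid of MB/K values; must bracket the critical region.
#' @param refine_step step of the refined central-difference grid used to
#'   localize the derivative maximum.
#' @return A list with `ratio` (grid midpoints), `delta_psi` (on
#'   `ratio_grid`), `derivative`, `peak_ratio` and `peak_sharpness` (the
#'   maximizer and maximum of the derivative), and `sharpness_at_1` (the
#'   derivative at MB/K = 1).
#' @export
sensitivity_curve <- function(K, theta = 180,
                              ratio_grid = seq(0.25, 1.75, by = 0.01),
                              refine_step = 1e-3) {
  if (any(ratio_grid <= 0)) stop_invalid("ratio_grid must be positive")
  if (min(ratio_grid) > 0.95 || max(ratio_grid) < 1.05)
    stop_invalid("ratio_grid must bracket the critical region around MB/K = 1")
  dp <- vapply(ratio_grid,
               function(r) deflection_statistics(r * K, K, theta)$delta_psi,
               numeric(1))
  nr <- length(ratio_grid)
  mid <- (ratio_grid[-1] + ratio_grid[-nr]) / 2
  der <- diff(dp) / diff(ratio_grid)
  # refine around the coarse maximum with central differences
  r0 <- mid[which.max(der)]
  span <- 3 * max(diff(ratio_grid))
  rfine <- seq(max(min(ratio_grid), r0 - span), min(max(ratio_grid), r0 + span),
               by = refine_step)
  h <- refine_step
  dfine <- vapply(rfine, function(r) {
    (deflection_statistics((r + h) * K, K, theta)$delta_psi -
       deflection_statistics((r - h) * K, K, theta)$delta_psi) / (2 * h)
  }, numeric(1))
  i <- which.max(dfine)
  h1 <- 1e-4
  s1 <- (deflection_statistics((1 + h1) * K, K, theta)$delta_psi -
           deflection_statistics((1 - h1) * K, K, theta)$delta_psi) / (2 * h1)
  list(ratio = mid, delta_psi = dp, derivative = der,
       peak_ratio = rfine[i], peak_sharpness = dfine[i],
       sharpness_at_1 = s1)
}

#' Minimum detectable deviation from antiparallel alignment
#'
#' Smallest angular deviation `eta` (degrees) from the antiparallel
#' configuration at which the change in the mean deflection exceeds the
#' thermal fluctuation amplitude of the deflection at the operating angle:
#' `|mean_psi(180 - eta) - mean_psi(180)| >= criterion * delta_psi(180 - eta)`.
#' Found by bisection to 0.01 degrees.  Operated at the critical point
#' (`K = MB`) unless overridden.  The noise is evaluated at the deflected
#' angle because that is where the transduced signal fluctuates; at the
#' critical point the fluctuation amplitude collapses rapidly once the
#' antiparallel symmetry is broken, which is what makes the critical
#' transducer a sensitive compass as well as an intensity sensor.
#'
#' @param MB magnetic energy (k_B T units).
#' @param K torsional stiffness (k_B T units); default `MB`.
#' @param criterion signal-to-noise factor in the detection criterion.
#' @return `eta` in degrees, or `NA` (with a warning) if the criterion is
#'   never met within 90 degrees.
#' @examples
#' minimum_detectable_angle(121)  # ~1 degree
#' minimum_detectable_angle(6)    # ~10 degrees
#' @export
minimum_detectable_angle <- function(MB, K = MB, criterion = 1) {
  base <- deflection_statistics(MB, K, 180)
  f <- function(eta) {
    ds <- deflection_statistics(MB, K, 180 - eta)
    abs(ds$mean_psi - base$mean_psi) - criterion * ds$delta_psi
  }
  if (f(90) < 0) {
    warning("deviation not detectable within 90 degrees")
    return(NA_real_)
  }
  lo <- 0; hi <- 90
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Full torque-transducer state
#'
#' Convenience wrapper assembling the deflection statistics, critical-point
#' sensitivity and minimum detectable angle for one `(MB, K, theta)`.
#'
#' @inheritParams deflection_statistics
#' @return A list of class `torque_transducer_state` with fields `MB`, `K`,
#'   `theta`, `mean_psi`, `delta_psi`, `sensitivity` (derivative of
#'   `delta_psi` with respect to MB/K at the operating ratio) and `eta`
#'   (degrees).
#' @export
torque_transducer_state <- function(MB, K, theta = 180) {
  ds <- deflection_statistics(MB, K, theta)
  h <- 1e-4
  r <- MB / K
  sens <- (deflection_statistics((r + h) * K, K, theta)$delta_psi -
             deflection_statistics((r - h) * K, K, theta)$delta_psi) / (2 * h)
  structure(list(MB = MB, K = K, theta = theta,
                 mean_psi = ds$mean_psi, delta_psi = ds$delta_psi,
                 sensitivity = sens,
                 eta = minimum_detectable_angle(MB, K)),
            class = "torque_transducer_state")
}

#' @export
print.torque_transducer_state <- function(x, ...) {
  cat(sprintf(
    "torque transducer: MB = %.3g kT, K = %.3g kT, theta = %g deg\n  mean psi %.4g rad, delta psi %.4g rad, sensitivity %.4g rad per MB/K, eta %.3g deg\n",
    x$MB, x$K, x$theta, x$mean_psi, x$delta_psi, x$sensitivity, x$eta))
  invisible(x)
}

#' Magnetic-energy statistics over a table of fossil moments
#'
#' Converts a table of morphology-labelled moments to `MB/k_B T` at the
#' given field and temperature and summarizes the distribution.
#'
#' @param records data frame with columns `label` (morphology class) and
#'   `moment` (A m^2); e.g. from [read_moment_table()].
#' @param field flux density (T); default 50 uT.
#' @param temperature temperature (K); default 298.
#' @param breaks histogram breaks passed to [hist()].
#' @return A list with `mb` (per-record energies), `mean`, `median`, `max`,
#'   and `histogram` (a `histogram` object, not plotted).
#' @export
fossil_energy_stats <- function(records, field = 50e-6, temperature = 298,
                                breaks = "Sturges") {
  if (is.null(records) || nrow(records) == 0)
    stop_invalid("records must be a nonempty data frame")
  if (!all(c("label", "moment") %in% names(records)))
    stop_invalid("records needs columns 'label' and 'moment'")
  mb <- mb_ratio(records$moment, field, temperature)
  list(mb = data.frame(label = records$label, MB = mb),
       mean = mean(mb), median = stats::median(mb), max = max(mb),
       histogram = graphics::hist(mb, breaks = breaks, plot = FALSE))
}

#' Read a CSV table of fossil moments
#'
#' Expects at least columns `label` and `moment` (A m^2).
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_moment_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "moment") %in% names(df)))
    stop_invalid("moment table needs columns 'label' and 'moment'")
  df
}
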