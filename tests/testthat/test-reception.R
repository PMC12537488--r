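kB <- 1.380649e-23

test_that("magnetic-to-thermal energy ratios reproduce the reference values", {
  # giant spearhead: 1e-14 A m^2 at 50 uT, 298 K -> 121.5, printed as 121
  expect_equal(mb_ratio(1e-14, 50e-6, 298), 121.5, tolerance = 1e-3)
  expect_equal(mb_ratio(1e-14, 50e-6, 298), 121, tolerance = 0.005)
  # trout-type nanoparticle cluster: 6.1, printed as 6
  expect_equal(mb_ratio(5e-16, 50e-6, 298), 6.1, tolerance = 0.005)
  expect_equal(mb_ratio(5e-16, 50e-6, 298), 6, tolerance = 0.02)
  # top of the receptor-cell moment range (1e-13 -> ~1200)
  expect_equal(mb_ratio(1e-13, 50e-6, 298), 1200, tolerance = 0.02)
  expect_equal(mb_ratio(0, 1, 300), 0)
  expect_error(mb_ratio(-1e-15, 50e-6, 298), "non-negative")
})

test_that("mb_ratio is linear in moment and field and inverse-linear in temperature", {
  base <- mb_ratio(2e-15, 40e-6, 300)
  expect_equal(mb_ratio(4e-15, 40e-6, 300), 2 * base)
  expect_equal(mb_ratio(2e-15, 80e-6, 300), 2 * base)
  expect_equal(mb_ratio(2e-15, 40e-6, 600), base / 2)
  expect_equal(base, 2e-15 * 40e-6 / (kB * 300))
})

test_that("needle moments follow the uniformly magnetized cylinder formula", {
  m <- needle_moment(100e-9, 2e-6)
  expect_equal(m, 4.80768e5 * pi * (50e-9)^2 * 2e-6)
  # the 100 nm x 2 um magnetite needle carries ~92 kT at 50 uT, 298 K
  expect_equal(round(mb_ratio(m, 50e-6, 298)), 92)
  expect_equal(needle_moment(1e-7, 0), 0)
  expect_equal(needle_moment(1e-7, 2e-6), 2 * needle_moment(1e-7, 1e-6))
})

test_that("deflection statistics match harmonic and quartic closed forms", {
  # harmonic limit: MB/K well below 1 -> sd = (K - MB)^(-1/2)
  ds <- deflection_statistics(0.5 * 121, 121, 180)
  expect_equal(ds$delta_psi, 1 / sqrt(60.5), tolerance = 0.05)
  expect_equal(ds$mean_psi, 0, tolerance = 1e-8)
  # quartic critical point MB = K
  dq <- deflection_statistics(121, 121, 180)
  quartic <- sqrt(sqrt(24 / 121) * gamma(3 / 4) / gamma(1 / 4))
  expect_equal(dq$delta_psi, quartic, tolerance = 0.05)
})

test_that("Boltzmann limits: stiff pivot freezes fluctuations; weak field gives the harmonic width", {
  expect_lt(deflection_statistics(0, 4000, 180)$delta_psi, 0.02)
  expect_equal(deflection_statistics(0, 121, 180)$delta_psi, 1 / sqrt(121),
               tolerance = 0.01)
  expect_equal(deflection_statistics(1e-9, 36, 180)$delta_psi, 1 / 6,
               tolerance = 0.01)
})

test_that("mean deflection is antisymmetric in the field angle", {
  for (th in c(30, 90, 150, 170)) {
    a <- deflection_statistics(50, 30, th)$mean_psi
    b <- deflection_statistics(50, 30, -th)$mean_psi
    expect_equal(a, -b, tolerance = 1e-8)
  }
  expect_equal(deflection_statistics(200, 121, 180)$mean_psi, 0,
               tolerance = 1e-6)
})

test_that("quadrature tolerance refinement leaves delta_psi unchanged", {
  for (r in c(0.5, 1, 1.5)) {
    a <- deflection_statistics(r * 121, 121, 180, rel.tol = 1e-8)$delta_psi
    b <- deflection_statistics(r * 121, 121, 180, rel.tol = 1e-12)$delta_psi
    expect_lt(abs(a - b) / a, 1e-6)
  }
})

test_that("the fluctuation amplitude rises most sharply close to MB/K = 1", {
  sc <- sensitivity_curve(121, ratio_grid = seq(0.5, 1.5, by = 0.02))
  expect_gt(sc$peak_ratio, 0.95)
  expect_lt(sc$peak_ratio, 1.25)
  expect_gt(sc$peak_sharpness, sc$sharpness_at_1 * 0.99)
  expect_error(sensitivity_curve(121, ratio_grid = seq(1.2, 1.5, 0.05)),
               "bracket")
})

test_that("critical-point sharpness grows like K^(1/4) at large K", {
  Ks <- c(100, 400, 1600, 6400)
  s <- vapply(Ks, function(K) sensitivity_curve(
    K, ratio_grid = seq(0.7, 1.3, by = 0.01))$peak_sharpness, numeric(1))
  slope <- coef(lm(log(s) ~ log(Ks)))[2]
  expect_equal(unname(slope), 0.25, tolerance = 0.2)  # 0.25 +/- 0.05
})

test_that("a stiff, strongly magnetic transducer resolves degree-scale deviations; a weak one only tens of degrees", {
  eta121 <- minimum_detectable_angle(121)
  eta6 <- minimum_detectable_angle(6)
  expect_lt(eta121, eta6)
  expect_gt(eta121, 0.1); expect_lt(eta121, 5)     # of order 1 degree
  expect_gt(eta6, 3); expect_lt(eta6, 40)          # of order 10 degrees
  st <- torque_transducer_state(121, 121)
  expect_equal(st$eta, eta121, tolerance = 0.02)
  expect_equal(st$mean_psi, 0, tolerance = 1e-6)
})

test_that("fossil energy statistics equal a brute-force recomputation from raw moments", {
  tab <- read_moment_table(system.file("extdata",
                                       "synthetic_moment_table.csv",
                                       package = "giantmag"))
  expect_equal(nrow(tab), 24)
  st <- fossil_energy_stats(tab, field = 50e-6, temperature = 298)
  manual <- tab$moment * 50e-6 / (kB * 298)
  expect_equal(st$mean, mean(manual))
  expect_equal(st$median, median(manual))
  expect_equal(st$max, max(manual))
  expect_s3_class(st$mb, "data.frame")
  single <- fossil_energy_stats(tab[3, ])
  expect_equal(single$mean, single$median)
  expect_equal(single$mean, single$max)
  expect_error(fossil_energy_stats(tab[0, ]), "nonempty")
})
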