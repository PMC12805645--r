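# Heat capacity (classical + quantum correction) and the glass transition.

test_that("central difference reproduces linear and quadratic enthalpies", {
  Tg <- seq(280, 400, by = 20)
  N <- 100
  H_lin <- thermo_series(Tg, 5e-21 * Tg, "enthalpy")
  c_lin <- classical_heat_capacity(H_lin, n_atoms = N)
  expect_equal(c_lin$y, rep(5e-21 / N / KBOLTZ, length(c_lin$T)),
               tolerance = 1e-10)

  a <- 1e-23
  H_sq <- thermo_series(Tg, a * Tg^2, "enthalpy")
  c_sq <- classical_heat_capacity(H_sq, n_atoms = N)
  # central difference is exact for quadratics: c(T) = 2 a T / N
  expect_equal(c_sq$y, 2 * a * c_sq$T / N / KBOLTZ, tolerance = 1e-10)

  expect_error(classical_heat_capacity(H_lin, N, dT = 30),
               "multiple of the grid step")
  expect_error(classical_heat_capacity(
    thermo_series(c(280, 300, 340), c(1, 2, 3), "enthalpy"), N),
    "uniform")
})

test_that("quantum correction matches Einstein closed forms and limits", {
  # Einstein mode at x = h nu0 / kB T = 1
  nu0 <- 10
  T1 <- PLANCK * nu0 * 1e12 / KBOLTZ
  es <- einstein_spectrum(nu0, dnu = 1e-4)
  expect_equal(delta_c_quantum(es, T1), einstein_delta_c(1),
               tolerance = 1e-8)
  # classical limit: x -> 0 gives delta_c -> 0
  expect_lt(delta_c_quantum(es, 1e6), 1e-4)
  # frozen limit: T -> 0 gives delta_c -> 1
  expect_equal(delta_c_quantum(es, 0.5), 1, tolerance = 1e-4)
  expect_error(delta_c_quantum(es, -10), "positive")
})

test_that("delta_c is bounded in [0, 1] and nonincreasing in T", {
  nu <- seq(0, 60, by = 0.25)
  sp <- vdos_spectrum(nu, smooth_g(nu))
  Ts <- c(50, 100, 200, 300, 400, 800, 2000)
  dc <- vapply(Ts, function(T) delta_c_quantum(sp, T), numeric(1))
  expect_true(all(dc >= 0 & dc <= 1))
  expect_true(all(diff(dc) < 0))
})

test_that("trapezoid quadrature agrees with an adaptive oracle", {
  nu <- seq(0, smooth_g_numax, length.out = 1e4)
  sp <- vdos_spectrum(nu, smooth_g(nu))
  T_K <- 300
  oracle <- stats::integrate(function(nu) {
    x <- PLANCK * nu * 1e12 / (KBOLTZ * T_K)
    (1 - einstein_c(x)) * smooth_g(nu)
  }, 0, smooth_g_numax, rel.tol = 1e-10)$value
  expect_equal(delta_c_quantum(sp, T_K), oracle, tolerance = 1e-6)
})

test_that("quantum heat capacity is the plain subtraction and lies below c_cl", {
  Tg <- seq(280, 400, by = 20)
  c_cl <- thermo_series(Tg[2:6], rep(3, 5), "heat_capacity")
  r0 <- quantum_heat_capacity(c_cl, 0)
  expect_equal(r0$c_qm, r0$c_cl)
  r <- quantum_heat_capacity(c_cl, 0.4)
  expect_true(all(r$c_qm < r$c_cl))
  expect_equal(r$c_qm, r$c_cl - r$delta_c)
  # Einstein mode at x = 1 with harmonic classical value 1 kB per mode
  expect_equal(quantum_heat_capacity(1, einstein_delta_c(1)),
               einstein_c(1), tolerance = 1e-12)
})

test_that("Tg is recovered from bilinear specific-volume data", {
  Tgrid <- seq(280, 800, by = 20)
  for (tg_true in c(625, 445)) {
    v <- gen_bilinear_v(Tgrid, tg_true, noise_sd = 0)
    r <- tg_from_specific_volume(v)
    expect_true(r$crossover)
    expect_lt(abs(r$Tg - tg_true), 20)     # within grid resolution
    expect_equal(unname(r$slopes), c(4e-8, 1.2e-7), tolerance = 1e-6)
  }
})

test_that("a single straight line is flagged as no crossover", {
  Tgrid <- seq(280, 800, by = 20)
  v <- thermo_series(Tgrid, 1e-4 + 4e-8 * Tgrid, "specific_volume")
  r <- tg_from_specific_volume(v)
  expect_false(r$crossover)
  expect_true(is.na(r$Tg))
  # equal slopes planted through the generator degenerate to one line
  v2 <- gen_bilinear_v(Tgrid, 625, slope_glass = 4e-8, slope_melt = 4e-8)
  expect_false(tg_from_specific_volume(v2)$crossover)
})

test_that("heat-capacity unit conversion is consistent", {
  # 1 kB per atom at the mean atomic mass of anhydroglucose (162/21 amu)
  expect_equal(heat_capacity_si(1, 162 / 21), KBOLTZ / (162 / 21 * AMU),
               tolerance = 1e-12)
})
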