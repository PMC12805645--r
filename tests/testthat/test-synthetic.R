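# Generators: determinism, ground-truth bookkeeping, validation.

test_that("generators are deterministic given the seed", {
  a <- gen_mode_trajectory(c(10), c(1), n_frames = 201, seed = 9)
  b <- gen_mode_trajectory(c(10), c(1), n_frames = 201, seed = 9)
  expect_identical(a$velocities, b$velocities)
  expect_false(identical(
    a$velocities,
    gen_mode_trajectory(c(10), c(1), n_frames = 201, seed = 10)$velocities))

  g1 <- gen_semicrystalline_config(Nc = 12, Nl = 12, d_target = 0.5,
                                   box = c(12, 12, 12), seed = 3)
  g2 <- gen_semicrystalline_config(Nc = 12, Nl = 12, d_target = 0.5,
                                   box = c(12, 12, 12), seed = 3)
  expect_identical(g1$configuration$sites, g2$configuration$sites)
  expect_identical(g1$crystal_mask, g2$crystal_mask)

  s1 <- gen_ate_series(100, 0.05, noise_sd = 1, seed = 5)
  s2 <- gen_ate_series(100, 0.05, noise_sd = 1, seed = 5)
  expect_identical(s1$dT, s2$dT)
})

test_that("mode trajectories equipartition kinetic energy across atoms", {
  tr <- gen_mode_trajectory(c(5, 20), c(0.5, 0.5), n_atoms = 5,
                            masses = c(1.008, 12.011, 15.999, 12.011, 1.008),
                            dt_out = 5e-4, n_frames = 10001, seed = 2)
  ke <- vapply(seq_len(tr$n_atoms), function(i)
    0.5 * tr$masses[i] * mean(rowSums(tr$velocities[, i, ]^2)), numeric(1))
  expect_lt(max(abs(ke / mean(ke) - 1)), 0.01)
})

test_that("mode-trajectory validation rejects bad specs", {
  expect_error(gen_mode_trajectory(numeric(0), numeric(0)), "at least one mode")
  expect_error(gen_mode_trajectory(c(10), c(0.5)), "sum to 1")
  # Nyquist for dt_out = 5e-4 ps is 1000 THz
  expect_error(gen_mode_trajectory(c(1000), c(1), dt_out = 5e-4), "Nyquist")
})

test_that("planted crystalline mask matches d_target to within one bundle", {
  for (d in c(0, 0.1, 0.25, 0.5, 1)) {
    g <- gen_semicrystalline_config(Nc = 40, Nl = 20, d_target = d,
                                    bundle_size = 4, box = c(15, 15, 15),
                                    seed = 7)
    n_sites <- 40 * 20
    expect_lte(abs(sum(g$crystal_mask) - d * n_sites), 4 * 20 / 2 + 1e-9)
  }
  expect_error(gen_semicrystalline_config(Nc = 1000, Nl = 100, d_target = 0,
                                          box = c(5, 5, 5), seed = 1),
               "larger box")
  expect_error(gen_semicrystalline_config(Nc = 8, Nl = 10, d_target = 1,
                                          bundle_size = 3,
                                          box = c(10, 10, 10), seed = 1),
               "bundle_size")
})

test_that("ATE series generator reproduces its parameters and validates", {
  s <- gen_ate_series(100, 0.05, fast_amp = 0, noise_sd = 0,
                      t_grid = seq(0, 0.3, length.out = 500))
  expect_equal(s$dT, 100 * exp(-s$t / 0.05), tolerance = 1e-12)
  expect_error(gen_ate_series(100, 0.05, noise_sd = -1), "noise_sd")
  expect_error(gen_ate_series(100, 0.05, t_grid = c(0, 0.2, 0.1)),
               "increasing")
  expect_error(gen_ate_series(100, 0.05, fast_amp = 5, fast_tau = 0.1),
               "fast_tau")
})

test_that("stress generator round-trips the elastic constants at zero noise", {
  st <- gen_stress_response(9, 4, 2, eps = 1e-3, noise_sd = 0,
                            n_samples = 1200)
  r44 <- c44_from_stress(st$shear_plus, st$reference, 1e-3)
  r44b <- c44_from_stress(st$shear_minus, st$reference, 1e-3,
                          method = "syy_minus")
  r <- c11_c12_from_stress(st$uniaxial_plus, st$uniaxial_minus, 1e-3)
  expect_equal(r44$C44, 2, tolerance = 1e-12)
  expect_equal(r44b$C44, 2, tolerance = 1e-12)
  expect_equal(r$C11, 9, tolerance = 1e-12)
  expect_equal(r$C12, 4, tolerance = 1e-12)
  expect_error(gen_stress_response(9, 4, 2, eps = 0), "eps")
})

test_that("bilinear specific-volume generator validates its breakpoint", {
  Tg <- seq(280, 800, by = 20)
  expect_s3_class(gen_bilinear_v(Tg, 625), "thermo_series")
  expect_error(gen_bilinear_v(Tg, 900), "inside")
  expect_error(gen_bilinear_v(Tg, 625, slope_glass = 2e-7, slope_melt = 1e-7),
               "slope")
})
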