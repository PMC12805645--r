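# VACF and VDOS: trivial limits, brute-force equivalence, spectral recovery.

test_that("constant and zero velocities give the expected VACF", {
  v <- array(0, dim = c(50, 1, 3))
  v[, 1, 1] <- 2; v[, 1, 2] <- -1             # constant velocity (2, -1, 0)
  tr <- trajectory(v, masses = 12, dt_out = 0.01, box = c(5, 5, 5))
  vac <- mass_weighted_vacf(tr, max_lag = 0.2, n_origins = 10)
  expect_equal(vac$psi, rep(12 * 5, length(vac$t)), tolerance = 1e-12)

  tr0 <- trajectory(array(0, dim = c(50, 2, 3)), masses = 1, dt_out = 0.01,
                    box = c(5, 5, 5))
  vac0 <- mass_weighted_vacf(tr0, max_lag = 0.2)
  expect_true(all(vac0$psi == 0))
  expect_error(vdos_from_vacf(vac0), "kinetic energy")
})

test_that("VACF equals the brute-force double-loop oracle", {
  tr <- gen_mode_trajectory(c(5, 40), c(0.4, 0.6), n_atoms = 3,
                            masses = c(1.008, 12.011, 15.999),
                            dt_out = 5e-4, n_frames = 301, seed = 4)
  vac <- mass_weighted_vacf(tr, max_lag = 0.05, n_origins = 20)
  n_lag <- length(vac$t) - 1L
  origins <- unique(round(seq(1, tr$n_frames - n_lag, length.out = 20)))
  expect_equal(vac$psi, bf_vacf(tr, n_lag, origins), tolerance = 1e-10)

  # single-atom cosine: psi proportional to cos(2 pi nu0 lag)
  t <- (0:400) * 5e-4
  v1 <- array(0, dim = c(401, 1, 3)); v1[, 1, 1] <- cos(2 * pi * 5 * t)
  tr1 <- trajectory(v1, 12, 5e-4, c(5, 5, 5))
  vac1 <- mass_weighted_vacf(tr1, max_lag = 0.05, n_origins = 50)
  bf <- bf_vacf(tr1, length(vac1$t) - 1L,
                unique(round(seq(1, 401 - (length(vac1$t) - 1L),
                                 length.out = 50))))
  expect_equal(vac1$psi, bf, tolerance = 1e-8)
})

test_that("spectrum transform matches the O(n^2) cosine-sum oracle", {
  tr <- gen_mode_trajectory(c(12, 77), c(0.5, 0.5), n_atoms = 2,
                            masses = c(12, 16), dt_out = 5e-4,
                            n_frames = 512, seed = 6)
  vac <- mass_weighted_vacf(tr, max_lag = 256 * 5e-4, n_origins = 25)
  for (win in c("hann", "none")) {
    sp <- vdos_from_vacf(vac, window = win)
    y <- vac$psi / vac$psi[1]
    if (win == "hann") {
      M <- length(y) - 1L
      y <- y * 0.5 * (1 + cos(pi * (0:M) / M))
    }
    g_bf <- bf_cosine_transform(y, 5e-4)
    g_bf[g_bf < 0] <- 0
    g_bf <- g_bf / pracma::trapz(sp$nu, g_bf)
    expect_equal(sp$g, g_bf, tolerance = 1e-8)
  }
})

test_that("spectra are normalized and peak positions are recovered exactly", {
  # on-grid frequency sweep: argmax bin must sit on the mode frequency
  M <- 200; dt <- 5e-4
  nyq <- 1 / (2 * dt)
  for (k in round(seq(5, M - 5, length.out = 20))) {
    nu0 <- k / (2 * M * dt)
    t <- (0:(4 * M)) * dt
    v <- array(0, dim = c(length(t), 1, 3))
    v[, 1, 1] <- cos(2 * pi * nu0 * t)
    tr <- trajectory(v, 12, dt, c(5, 5, 5))
    sp <- vdos_from_vacf(mass_weighted_vacf(tr, max_lag = M * dt,
                                            n_origins = 40))
    expect_equal(pracma::trapz(sp$nu, sp$g), 1, tolerance = 1e-6)
    expect_equal(sp$nu[which.max(sp$g)], nu0, tolerance = 1e-9)
  }
  expect_equal(max(sp$nu), nyq, tolerance = 1e-9)
})

test_that("a single on-grid mode concentrates its spectral weight", {
  tr <- gen_mode_trajectory(c(10), c(1), n_atoms = 4,
                            masses = c(12, 16, 1, 12), dt_out = 5e-4,
                            n_frames = 4001, seed = 11)
  sp <- vdos_from_vacf(mass_weighted_vacf(tr, max_lag = 1, n_origins = 200))
  dnu <- sp$nu[2] - sp$nu[1]
  sel <- abs(sp$nu - 10) <= 2.5 * dnu
  expect_gt(pracma::trapz(sp$nu[sel], sp$g[sel]), 0.99)
})

test_that("white-noise velocities give a flat spectrum", {
  ratios <- vapply(1:10, function(s) {
    v <- withr::with_seed(s, array(stats::rnorm(600 * 100 * 3),
                                   dim = c(600, 100, 3)))
    tr <- trajectory(v, 12, 5e-4, c(5, 5, 5))
    sp <- vdos_from_vacf(mass_weighted_vacf(tr, max_lag = 64 * 5e-4,
                                            n_origins = 150))
    max(sp$g) / min(sp$g[sp$g > 0])
  }, numeric(1))
  expect_lt(mean(ratios), 1.5)
})

test_that("the pipeline wrapper enforces its duration contract", {
  tr <- gen_mode_trajectory(c(10), c(1), n_frames = 2001, dt_out = 5e-4,
                            seed = 1)   # 1 ps
  expect_error(vdos_pipeline(tr), "shorter")
  sp <- vdos_pipeline(tr, min_duration = 1)
  expect_equal(pracma::trapz(sp$nu, sp$g), 1, tolerance = 1e-6)
  expect_error(mass_weighted_vacf(tr, max_lag = 2), "duration")
})
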