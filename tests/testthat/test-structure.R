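# Structure factor, P2 crystallinity protocol, chain geometry.

test_that("P2 takes its canonical values", {
  expect_equal(p2_order(c(1, 0, 0), c(2, 0, 0)), 1)
  expect_equal(p2_order(c(1, 0, 0), c(-3, 0, 0)), 1)   # sign-blind
  expect_equal(p2_order(c(1, 0, 0), c(0, 1, 0)), -0.5)
  th <- 10 * pi / 180
  expect_equal(round(p2_order(c(1, 0, 0), c(cos(th), sin(th), 0)), 2), 0.95)
  expect_error(p2_order(c(0, 0, 0), c(1, 0, 0)), "zero vector")
})

test_that("segment partition follows the integer arithmetic of the protocol", {
  g <- gen_semicrystalline_config(Nc = 10, Nl = 50, d_target = 0,
                                  box = c(20, 20, 20), seed = 1)
  p <- partition_segments(g$configuration, lp = 3.4, monomer_spacing = 0.6)
  expect_equal(attr(p, "monomers_per_segment"), 6)     # round(3.4/0.6)
  expect_length(p[[1]]$sites, 8)                       # 50 %/% 6
  expect_equal(nrow(p[[1]]$vec), 8)
  expect_equal(sum(lengths(p[[1]]$sites[[1]])), 6)
  # Nl = 6 gives exactly one segment
  g6 <- gen_semicrystalline_config(Nc = 10, Nl = 6, d_target = 0,
                                   box = c(12, 12, 12), seed = 2)
  p6 <- partition_segments(g6$configuration)
  expect_equal(nrow(p6[[1]]$vec), 1)
  expect_error(partition_segments(g$configuration, lp = 0.5,
                                  monomer_spacing = 0.6), "2 monomer")
})

test_that("single scatterer and uniform random sites bracket S(k)", {
  c1 <- configuration(matrix(c(1, 2, 3), 1), 1, 1, c(10, 10, 10))
  sk1 <- structure_factor(c1, k_max = 8)
  expect_true(all(abs(sk1$S - 1) < 1e-12))
  expect_error(structure_factor(c1, k_max = 0.1), "reciprocal")

  ru <- withr::with_seed(2, configuration(matrix(stats::runif(600) * 8, 200),
                                          rep(1:10, each = 20),
                                          rep(1:20, 10), c(8, 8, 8)))
  skr <- structure_factor(ru, k_max = 15)
  hi <- skr$k > 3 * 2 * pi / 8
  expect_true(all(abs(skr$S[hi] - 1) < 3 / sqrt(skr$n_k[hi]) + 0.35))
  expect_lt(abs(mean(skr$S[hi]) - 1), 0.05)
})

test_that("a 1D lattice produces its Bragg peak at the lattice vector", {
  n <- 64
  cl <- configuration(cbind(0.6 * (0:(n - 1)), 0, 0), rep(1, n), 1:n,
                      c(38.4, 5, 5))
  k_bragg <- 2 * pi / 0.6                               # 10.47 nm^-1
  expect_equal(structure_factor_at(cl, c(k_bragg, 0, 0)), n,
               tolerance = 1e-9)
  # off-Bragg commensurate vectors are extinguished
  expect_lt(structure_factor_at(cl, c(2 * pi * 32 / 38.4, 0, 0)), 1e-12)
  expect_lt(structure_factor_at(cl, c(2 * pi * 96 / 38.4, 0, 0)), 1e-12)
})

test_that("planted semi-crystalline samples show the interchain correlation peak", {
  g <- gen_semicrystalline_config(Nc = 32, Nl = 24, d_target = 1,
                                  bond = 0.6, bundle_size = 16,
                                  box = c(15, 15, 15), seed = 5)
  sk <- structure_factor(g$configuration, k_max = 17)
  dk <- sk$k[2] - sk$k[1]
  # interchain stacking at 0.43 nm -> local maximum near 14.6 nm^-1
  win <- sk$k > 12.5 & sk$k < 16.5
  k_peak <- sk$k[win][which.max(sk$S[win])]
  expect_lt(abs(k_peak - 2 * pi / 0.43), dk + 1e-9)
  # intrachain repeat at 0.6 nm -> peak near 10.5 nm^-1
  win2 <- sk$k > 9 & sk$k < 12
  k_peak2 <- sk$k[win2][which.max(sk$S[win2])]
  expect_lt(abs(k_peak2 - 2 * pi / 0.6), dk + 1e-9)
})

test_that("crystallite detection obeys the four-chain rule", {
  # 3 straight parallel chains only: below min_chains, d = 0
  mk_straight <- function(n_chains, spacing = 0.43, Nl = 12) {
    sites <- do.call(rbind, lapply(seq_len(n_chains), function(c)
      cbind(0.6 * (0:(Nl - 1)), c * spacing, 0)))
    configuration(sites, rep(seq_len(n_chains), each = Nl),
                  rep(seq_len(Nl), n_chains), c(30, 30, 30))
  }
  r3 <- detect_crystallites(mk_straight(3))
  expect_equal(r3$d, 0)
  r4 <- detect_crystallites(mk_straight(4))
  expect_equal(r4$d, 1)                                 # Nl = 12 = 2 segments
  expect_length(r4$crystallites, 1)
})

test_that("planted crystallinity is recovered and the null stays clean", {
  g <- gen_semicrystalline_config(Nc = 100, Nl = 50, d_target = 0.2,
                                  box = c(22, 22, 22), seed = 3)
  r <- detect_crystallites(g$configuration)
  expect_lt(abs(r$d - 0.2), 0.03)
  # detected sites sit essentially inside the planted mask (an occasional
  # amorphous segment brushing a bundle may be admitted legitimately)
  leak <- sum(r$site_mask & !g$crystal_mask)
  expect_lt(leak / sum(g$crystal_mask), 0.02)
  # isotropic null melts: d < 0.02 across seeds
  for (s in 1:3) {
    gn <- gen_semicrystalline_config(Nc = 60, Nl = 50, d_target = 0,
                                     box = c(20, 20, 20), seed = 20 + s)
    expect_lt(detect_crystallites(gn$configuration)$d, 0.02)
  }
})

test_that("d is exactly invariant under rigid rotation plus translation", {
  g <- gen_semicrystalline_config(Nc = 24, Nl = 24, d_target = 0.5,
                                  bundle_size = 4, box = c(60, 60, 60),
                                  seed = 9)
  conf <- g$configuration
  conf$sites <- sweep(conf$sites, 2, c(25, 25, 25), `+`)  # keep compact, centred
  r0 <- detect_crystallites(conf)
  rot <- rotate_configuration(conf, axis = c(1, 2, 3), angle = 0.7,
                              shift = c(1.3, -2.1, 0.4))
  r1 <- detect_crystallites(rot)
  expect_identical(r1$d, r0$d)
  expect_identical(r1$n_crystal, r0$n_crystal)
})

test_that("no monomer is double counted across crystallites", {
  g <- gen_semicrystalline_config(Nc = 40, Nl = 24, d_target = 0.6,
                                  box = c(25, 25, 25), seed = 13)
  r <- detect_crystallites(g$configuration)
  all_sites <- unlist(lapply(r$crystallites, `[[`, "sites"))
  expect_equal(length(all_sites), length(unique(all_sites)))
  expect_equal(length(all_sites), r$n_crystal)
})

test_that("detected d grows monotonically with the planted fraction", {
  ds <- vapply(c(0, 0.1, 0.2, 0.4, 1), function(d) {
    g <- gen_semicrystalline_config(Nc = 60, Nl = 48, d_target = d,
                                    box = c(20, 20, 20), seed = 17)
    detect_crystallites(g$configuration)$d
  }, numeric(1))
  expect_true(all(diff(ds) >= 0))
  expect_equal(ds[1], 0)
  expect_equal(ds[5], 1)     # Nl = 48 divisible by the 6-monomer segment
})

test_that("persistence length closes the generator loop and flags edge cases", {
  g <- gen_semicrystalline_config(Nc = 200, Nl = 50, d_target = 0,
                                  box = c(30, 30, 30), seed = 8)
  lp <- persistence_length(g$configuration)
  expect_equal(lp$flag, "ok")
  expect_lt(abs(lp$lp / 3.4 - 1), 0.05)
  # straight chains: correlation does not decay
  straight <- gen_semicrystalline_config(Nc = 12, Nl = 24, d_target = 1,
                                         bundle_size = 4, box = c(30, 30, 30),
                                         seed = 4)
  rs <- persistence_length(straight$configuration)
  expect_equal(rs$flag, "exceeds measurable range")
  expect_true(is.na(rs$lp))
  expect_gt(rs$lower_bound, 10)
  # freely-jointed chains decorrelate within ~1 bond
  fjc <- gen_semicrystalline_config(Nc = 50, Nl = 30, d_target = 0,
                                    lp_target = 0.05, box = c(25, 25, 25),
                                    seed = 6)
  rf <- persistence_length(fjc$configuration)
  expect_lt(rf$lp, 1.5 * 0.6)
  expect_error(persistence_length(gen_semicrystalline_config(
    Nc = 5, Nl = 10, d_target = 0, box = c(10, 10, 10),
    seed = 1)$configuration), "10 chains")
})

test_that("end-to-end distances match straight-chain and WLC references", {
  sites <- cbind(0.6 * (0:49), 0, 0)
  straight <- configuration(sites, rep(1, 50), 1:50, c(40, 10, 10))
  # needs >= 1 chain; replicate to several parallel chains
  many <- configuration(rbind(sites, sweep(sites, 2, c(0, 2, 0), `+`)),
                        rep(1:2, each = 50), rep(1:50, 2), c(40, 10, 10))
  expect_equal(end_to_end(many)$mean_ree, 49 * 0.6, tolerance = 1e-12)

  g <- gen_semicrystalline_config(Nc = 500, Nl = 50, d_target = 0,
                                  box = c(40, 40, 40), seed = 1)
  r2 <- end_to_end(g$configuration)$mean_r2
  expect_lt(abs(r2 / kratky_porod_r2(3.4, 49 * 0.6) - 1), 0.05)

  withone <- configuration(rbind(sites, c(0, 5, 0)), c(rep(1, 50), 2),
                           c(1:50, 1), c(40, 10, 10), allow_ragged = TRUE)
  expect_warning(ee <- end_to_end(withone), "excluded")
  expect_equal(ee$mean_ree, 49 * 0.6, tolerance = 1e-12)
})

test_that("wrapped coordinates are repaired by unwrapping, or rejected", {
  g <- gen_semicrystalline_config(Nc = 12, Nl = 30, d_target = 0,
                                  box = c(9, 9, 9), seed = 5)
  conf <- g$configuration
  wrapped <- conf
  wrapped$sites <- conf$sites %% matrix(conf$box, nrow(conf$sites), 3,
                                        byrow = TRUE)
  expect_error(end_to_end(wrapped, unwrap = FALSE), "unwrap")
  ee_w <- end_to_end(wrapped)        # min-image repair
  ee_u <- end_to_end(conf)
  expect_equal(ee_w$mean_ree, ee_u$mean_ree, tolerance = 1e-9)
})
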