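# Seeded synthetic-data generators. Every input the pipeline consumes can
# be generated here with known ground truth, so each analysis stage closes
# a generator/estimator loop without an MD engine. All generators are
# deterministic given their seed.

.with_seed <- function(seed, code) withr::with_seed(seed, code)

# orthonormal frame with a uniformly distributed first axis
.rand_frame <- function() {
  repeat {
    u <- stats::rnorm(3)
    n <- sqrt(sum(u^2))
    if (n > 1e-12) { u <- u / n; break }
  }
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(u = u, e1 = e1, e2 = e2)
}

#' Synthetic trajectory with a prescribed mode spectrum
#'
#' Each atom's velocity is a superposition of cosines at `mode_freqs` with
#' independent uniform random phases per atom/mode/component and amplitudes
#' proportional to sqrt(weight/mass), so the recovered VDOS concentrates
#' weight `mode_weights[j]` at `mode_freqs[j]` and the time-averaged kinetic
#' energy is the same for every atom.
#'
#' @param mode_freqs mode frequencies (THz), all below the Nyquist frequency
#'   `1/(2 dt_out)`.
#' @param mode_weights nonnegative weights summing to 1 (within 1e-12).
#' @param n_atoms number of atoms.
#' @param masses per-atom masses (amu), scalar or length `n_atoms`.
#' @param dt_out output interval (ps).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param box box lengths (nm), metadata only.
#' @return a [trajectory()].
#' @export
gen_mode_trajectory <- function(mode_freqs, mode_weights, n_atoms = 4,
                                masses = 12.011, dt_out = 5e-4,
                                n_frames = 2001, seed = 1,
                                box = c(20, 20, 20)) {
  if (length(mode_freqs) == 0) stop("at least one mode is required")
  if (length(mode_weights) != length(mode_freqs))
    stop("mode_weights must match mode_freqs in length")
  if (any(mode_weights < 0)) stop("mode weights must be nonnegative")
  if (abs(sum(mode_weights) - 1) > 1e-12)
    stop("mode weights must sum to 1 (within 1e-12)")
  nyquist <- 1 / (2 * dt_out)
  if (any(mode_freqs >= nyquist))
    stop("mode frequency at or above the Nyquist frequency (", nyquist, " THz)")
  if (length(masses) == 1L) masses <- rep(masses, n_atoms)
  stopifnot(length(masses) == n_atoms, all(masses > 0))
  t <- (0:(n_frames - 1)) * dt_out
  v <- array(0, dim = c(n_frames, n_atoms, 3))
  .with_seed(seed, {
    for (j in seq_along(mode_freqs)) {
      amp <- sqrt(mode_weights[j] / masses)       # per atom
      phase <- matrix(stats::runif(n_atoms * 3, 0, 2 * pi), n_atoms, 3)
      wt <- 2 * pi * mode_freqs[j] * t
      for (d in 1:3) {
        # cos(w t + phi) = cos(wt) cos(phi) - sin(wt) sin(phi)
        v[, , d] <- v[, , d] +
          outer(cos(wt), amp * cos(phase[, d])) -
          outer(sin(wt), amp * sin(phase[, d]))
      }
    }
  })
  trajectory(v, masses, dt_out, box)
}

#' Synthetic semi-crystalline chain assembly with known crystalline mask
#'
#' A fraction `d_target` of the chains (rounded to whole bundles of
#' `bundle_size` chains) is placed as straight, parallel chains on a square
#' `interchain_spacing` grid -- emulating crystallites and producing an
#' interchain correlation peak near 2 pi / 0.43 = 14.6 nm^-1 -- while the
#' remaining chains are worm-like random walks with persistence length
#' `lp_target` (successive bond directions at fixed polar angle
#' acos(exp(-bond/lp)) and uniform azimuth, so <cos theta(s)> =
#' exp(-s bond/lp) exactly in expectation).
#'
#' @param Nc number of chains.
#' @param Nl monomers per chain.
#' @param d_target crystalline monomer fraction between 0 and 1.
#' @param bond monomer spacing (nm).
#' @param lp_target persistence length of the amorphous chains (nm).
#' @param bundle_size chains per crystallite (>= 4).
#' @param interchain_spacing chain spacing inside a bundle (nm).
#' @param box box lengths (nm).
#' @param seed integer seed.
#' @return list with `configuration` (a [configuration()], unwrapped
#'   coordinates) and `crystal_mask` (logical per site, the ground truth).
#' @export
gen_semicrystalline_config <- function(Nc, Nl, d_target, bond = 0.6,
                                       lp_target = 3.4, bundle_size = 4,
                                       interchain_spacing = 0.43,
                                       box = c(20, 20, 20), seed = 1) {
  stopifnot(Nc >= 1, Nl >= 2, d_target >= 0, d_target <= 1)
  if (bundle_size < 4) stop("bundle_size must be >= 4 (minimum crystallite)")
  if (Nc * Nl / prod(box) > 30)
    stop("infeasible packing: ", Nc * Nl, " sites in ", prod(box),
         " nm^3; use a larger box")
  n_bundles <- round(d_target * Nc / bundle_size)
  n_bundles <- min(n_bundles, floor(Nc / bundle_size))
  n_cryst_chains <- n_bundles * bundle_size
  if (d_target == 1 && n_cryst_chains < Nc && Nc %% bundle_size == 0)
    n_cryst_chains <- Nc
  sites <- matrix(0, Nc * Nl, 3)
  chain_id <- rep(seq_len(Nc), each = Nl)
  monomer_id <- rep(seq_len(Nl), Nc)
  mask <- rep(FALSE, Nc * Nl)
  g <- exp(-bond / lp_target)
  theta0 <- acos(min(1, g))
  .with_seed(seed, {
    chain <- 0L
    ncolg <- ceiling(sqrt(bundle_size))
    for (b in seq_len(n_bundles)) {
      fr <- .rand_frame()
      centre <- stats::runif(3) * box
      for (cidx in seq_len(bundle_size)) {
        chain <- chain + 1L
        i <- (cidx - 1) %% ncolg
        j <- (cidx - 1) %/% ncolg
        off <- (i - (ncolg - 1) / 2) * interchain_spacing * fr$e1 +
               (j - (ncolg - 1) / 2) * interchain_spacing * fr$e2
        k <- (0:(Nl - 1)) - (Nl - 1) / 2
        rows <- which(chain_id == chain)
        sites[rows, ] <- matrix(centre + off, Nl, 3, byrow = TRUE) +
          outer(k * bond, fr$u)
        mask[rows] <- TRUE
      }
    }
    while (chain < Nc) {
      chain <- chain + 1L
      rows <- which(chain_id == chain)
      x <- stats::runif(3) * box
      u <- .rand_frame()$u
      pts <- matrix(0, Nl, 3)
      pts[1, ] <- x
      for (m in 2:Nl) {
        fr <- .rand_frame_about(u)
        phi <- stats::runif(1, 0, 2 * pi)
        u <- cos(theta0) * u +
          sin(theta0) * (cos(phi) * fr$e1 + sin(phi) * fr$e2)
        u <- u / sqrt(sum(u^2))
        pts[m, ] <- pts[m - 1, ] + bond * u
      }
      sites[rows, ] <- pts
    }
  })
  list(configuration = configuration(sites, chain_id, monomer_id, box),
       crystal_mask = mask)
}

# orthonormal complement of a given unit vector
.rand_frame_about <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Synthetic approach-to-equilibrium decay series
#'
#' dT(t) = dT0 exp(-t/tau) + fast_amp exp(-t/fast_tau) + N(0, noise_sd),
#' emulating a microcanonical hot/cold relaxation with a fast initial
#' intramolecular transient.
#'
#' @param dT0 slow-component amplitude (K).
#' @param tau slow decay constant (ns), the ground truth for the fit.
#' @param fast_amp fast-transient amplitude (K); 0 disables it.
#' @param fast_tau fast decay constant (ns), < `tau`.
#' @param noise_sd Gaussian noise (K), >= 0.
#' @param t_grid time grid (ns), strictly increasing.
#' @param seed integer seed.
#' @param Lx,A_cross,c_total sample geometry and extensive heat capacity
#'   (SI) carried into the [ate_series()].
#' @export
gen_ate_series <- function(dT0, tau, fast_amp = 0, fast_tau = tau / 10,
                           noise_sd = 0, t_grid = seq(0, 0.3, length.out = 1800),
                           seed = 1, Lx = 20e-9, A_cross = 400e-18,
                           c_total = 2.6e-17) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  if (fast_amp != 0 && !(tau > fast_tau && fast_tau > 0))
    stop("require tau > fast_tau > 0")
  dT <- dT0 * exp(-t_grid / tau) + fast_amp * exp(-t_grid / fast_tau)
  if (noise_sd > 0)
    dT <- dT + .with_seed(seed, stats::rnorm(length(t_grid), 0, noise_sd))
  ate_series(t_grid, dT, Lx, A_cross, c_total)
}

#' Synthetic stress responses for the strain protocols
#'
#' Linear elastic responses with independent Gaussian noise per sample:
#' uniaxial +/- eps give sxx = +/- C11 eps and syy = szz = +/- C12 eps; the
#' volume-conserving shear gives sxx(+eps) = +2 C44 eps and, mirroring the
#' negative-shear estimator, syy(-eps) = -2 C44 eps. The reference record is
#' pure noise.
#'
#' @param C11,C12,C44 ground-truth elastic constants (GPa).
#' @param eps strain magnitude (> 0).
#' @param noise_sd stress noise (GPa).
#' @param n_samples samples per record.
#' @param seed integer seed.
#' @param dt_ps sampling interval (ps).
#' @return named list of [stress_record()]s: `reference`, `uniaxial_plus`,
#'   `uniaxial_minus`, `shear_plus`, `shear_minus`.
#' @export
gen_stress_response <- function(C11, C12, C44, eps = 1e-3, noise_sd = 0,
                                n_samples = 1000, seed = 1, dt_ps = 0.1) {
  if (eps <= 0) stop("eps must be positive (zero strain gives no signal)")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  t <- (seq_len(n_samples) - 1) * dt_ps
  .with_seed(seed, {
    nz <- function() if (noise_sd > 0) stats::rnorm(n_samples, 0, noise_sd) else 0
    list(
      reference = stress_record(t, 0 + nz(), 0 + nz(), 0 + nz(), "reference"),
      uniaxial_plus = stress_record(t, C11 * eps + nz(), C12 * eps + nz(),
                                    C12 * eps + nz(), "uniaxial_plus"),
      uniaxial_minus = stress_record(t, -C11 * eps + nz(), -C12 * eps + nz(),
                                     -C12 * eps + nz(), "uniaxial_minus"),
      shear_plus = stress_record(t, 2 * C44 * eps + nz(), -2 * C44 * eps + nz(),
                                 0 + nz(), "shear_volume_conserving"),
      shear_minus = stress_record(t, -2 * C44 * eps + nz(),
                                  -2 * C44 * eps + nz(), 0 + nz(),
                                  "shear_minus"))
  })
}

#' Synthetic bilinear specific-volume curve
#'
#' Piecewise-linear v(T), continuous at the planted glass transition `Tg`,
#' plus Gaussian noise.
#'
#' @param T_grid temperature grid (K), strictly increasing; must bracket Tg.
#' @param Tg planted glass-transition temperature (K).
#' @param slope_glass,slope_melt specific-volume slopes below/above Tg
#'   (m^3 kg^-1 K^-1), both positive, `slope_melt >= slope_glass` (equal
#'   slopes produce a single line, i.e. no crossover).
#' @param v_at_Tg specific volume at Tg (m^3/kg).
#' @param noise_sd Gaussian noise (m^3/kg).
#' @param seed integer seed.
#' @return a [thermo_series()] labelled `"specific_volume"`.
#' @export
gen_bilinear_v <- function(T_grid, Tg, slope_glass = 4e-8, slope_melt = 1.2e-7,
                           v_at_Tg = 7.2e-4, noise_sd = 0, seed = 1) {
  if (any(diff(T_grid) <= 0)) stop("T_grid must be strictly increasing")
  if (Tg <= min(T_grid) || Tg >= max(T_grid))
    stop("Tg must lie strictly inside the temperature grid")
  if (slope_glass <= 0 || slope_melt < slope_glass)
    stop("require slope_melt >= slope_glass > 0")
  v <- ifelse(T_grid <= Tg, v_at_Tg + slope_glass * (T_grid - Tg),
              v_at_Tg + slope_melt * (T_grid - Tg))
  if (noise_sd > 0)
    v <- v + .with_seed(seed, stats::rnorm(length(T_grid), 0, noise_sd))
  thermo_series(T_grid, v, label = "specific_volume")
}

#' Consistent synthetic input bundle for the full conductivity workflow
#'
#' Fans one integer seed out to per-generator streams and returns every
#' input [run_kappa_workflow()] needs, together with the ground truth used
#' to generate it. The defaults emulate a dense amorphous cellulose-like
#' sample at 300 K: mass density 1390 kg/m^3, mean atomic mass 7.71 amu
#' (anhydroglucose C6H10O5 has 21 atoms of total mass 162 amu), elastic
#' constants of a few GPa, a classical enthalpy slope of 3 k_B per atom.
#'
#' @param seed integer seed.
#' @param T_K working temperature (K).
#' @param n_atoms_traj atoms in the mode trajectory (analysis cost only).
#' @param n_frames frames in the mode trajectory.
#' @param mode_freqs,mode_weights prescribed spectrum (THz / fractions).
#' @param C11,C12,C44 planted elastic constants (GPa).
#' @param rho_m mass density (kg/m^3).
#' @param mean_mass_amu mean atomic mass (amu).
#' @param N_total total atom count of the emulated sample (sets the
#'   extensive heat capacity c_total = 3 N k_B).
#' @param tau_ns planted ATE decay constant (ns).
#' @param eps strain magnitude.
#' @param stress_noise_GPa,ate_noise_K noise levels.
#' @return list of inputs plus a `truth` sub-list.
#' @export
gen_kappa_bundle <- function(seed = 1, T_K = 300,
                             n_atoms_traj = 6, n_frames = 8001,
                             mode_freqs = c(2, 5, 15, 30, 60),
                             mode_weights = c(0.3, 0.25, 0.2, 0.15, 0.1),
                             C11 = 9, C12 = 4, C44 = 2,
                             rho_m = 1390, mean_mass_amu = 162 / 21,
                             N_total = 6.3e5, tau_ns = 0.05, eps = 1e-3,
                             stress_noise_GPa = 0.005, ate_noise_K = 1) {
  masses <- rep(c(12.011, 15.999, 1.008), length.out = n_atoms_traj)
  traj <- gen_mode_trajectory(mode_freqs, mode_weights, n_atoms = n_atoms_traj,
                              masses = masses, dt_out = 5e-4,
                              n_frames = n_frames, seed = seed)
  Tgrid <- seq(280, 400, by = 20)
  H <- thermo_series(Tgrid, 3 * N_total * .KBOLTZ * Tgrid, label = "enthalpy")
  stress <- gen_stress_response(C11, C12, C44, eps = eps,
                                noise_sd = stress_noise_GPa,
                                n_samples = 1500, seed = seed + 1)
  c_total <- 3 * N_total * .KBOLTZ
  ate <- gen_ate_series(dT0 = 100, tau = tau_ns, fast_amp = 20,
                        fast_tau = 0.005, noise_sd = ate_noise_K,
                        seed = seed + 2, Lx = 20e-9, A_cross = 400e-18,
                        c_total = c_total)
  rho_N <- rho_m / (mean_mass_amu * .AMU)
  list(trajectory = traj, enthalpy = H, stress = stress, ate = ate,
       T_K = T_K, eps = eps, rho_m = rho_m, rho_N = rho_N,
       n_atoms = N_total, mean_mass_amu = mean_mass_amu,
       stress_window = c(50, 150),
       truth = list(mode_freqs = mode_freqs, mode_weights = mode_weights,
                    C11 = C11, C12 = C12, C44 = C44, tau_ns = tau_ns,
                    c_cl_kB = 3))
}
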