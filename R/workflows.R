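# End-to-end orchestration: compose the spectra, thermo, elasticity and
# transport stages into the two headline analyses, with an effective-config
# echo in every report so runs are reproducible artifacts.

.default_kappa_config <- function() {
  list(vacf_max_lag_ps = NULL, vacf_n_origins = NULL, vdos_window = "hann",
       heatcap_dT_K = NULL, stress_window_ps = c(50, 150),
       ate_window_ns = c(0.02, 0.20), modes_per_atom = 3)
}

.merge_config <- function(defaults, config) {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(config)] <- config
  defaults
}

#' Full thermal-conductivity workflow on one sample
#'
#' Runs the complete chain: VDOS from the velocity trajectory; classical
#' heat capacity from the enthalpy series; quantum correction from the
#' spectrum; elastic constants from the stress records and sound velocities
#' from them; then the four conductivity variants -- the
#' minimum-conductivity model (quantum by construction) and the ATE route
#' with classical and with quantum-corrected heat capacity. Missing elastic
#' input skips the kappa_min branch with a warning; missing ATE input skips
#' the ATE branch.
#'
#' @param inputs list as produced by [gen_kappa_bundle()]: `trajectory`,
#'   `enthalpy` ([thermo_series()], J), `stress` (named record list),
#'   `ate` ([ate_series()]), `T_K`, `eps`, `rho_m`, `rho_N`, `n_atoms`,
#'   `mean_mass_amu`. Any of `trajectory`/`stress`/`ate` may be `NULL`.
#' @param config named list overriding entries of the default config:
#'   `vacf_max_lag_ps`, `vacf_n_origins`, `vdos_window`, `heatcap_dT_K`,
#'   `stress_window_ps`, `ate_window_ns`, `modes_per_atom` (3: the
#'   per-mode quantum correction is scaled to the 3 vibrational modes per
#'   atom so it applies to a per-atom classical heat capacity).
#' @return list report: `spectrum`, `heat_capacity` (T, c_cl, delta_c, c_qm
#'   in k_B/atom at the working temperature), `elastic` ([elastic_set()]),
#'   `velocities`, `kappa` (named values, W m^-1 K^-1), `config`.
#' @export
run_kappa_workflow <- function(inputs, config = list()) {
  cfg <- .merge_config(.default_kappa_config(), config)
  T_K <- inputs$T_K
  report <- list(T_K = T_K, config = cfg)

  spec <- NULL
  if (!is.null(inputs[["trajectory"]])) {
    spec <- vdos_from_vacf(
      mass_weighted_vacf(inputs[["trajectory"]], cfg$vacf_max_lag_ps,
                         cfg$vacf_n_origins),
      window = cfg$vdos_window)
    report$spectrum <- spec
  }

  c_cl_series <- classical_heat_capacity(inputs$enthalpy, inputs$n_atoms,
                                         dT = cfg$heatcap_dT_K)
  iT <- which.min(abs(c_cl_series$T - T_K))
  c_cl <- c_cl_series$y[iT]
  delta_c <- if (!is.null(spec)) cfg$modes_per_atom * delta_c_quantum(spec, T_K) else 0
  c_qm <- quantum_heat_capacity(c_cl, delta_c)
  report$heat_capacity <- list(T = c_cl_series$T[iT], c_cl = c_cl,
                               delta_c = delta_c, c_qm = c_qm)

  es <- NULL
  if (!is.null(inputs[["stress"]])) {
    st <- inputs[["stress"]]
    r44 <- c44_from_stress(st$shear_plus, st$reference, inputs$eps,
                           window = cfg$stress_window_ps)
    r44b <- c44_from_stress(st$shear_minus, st$reference, inputs$eps,
                            window = cfg$stress_window_ps,
                            method = "syy_minus")
    r1112 <- c11_c12_from_stress(st$uniaxial_plus, st$uniaxial_minus,
                                 inputs$eps, window = cfg$stress_window_ps)
    es <- elastic_set(T_K, r1112$C11, r1112$C12, r44$C44, inputs$rho_m,
                      sd_C11 = r1112$sd_C11, sd_C12 = r1112$sd_C12,
                      sd_C44 = r44$sd)
    report$elastic <- es
    report$c44_consistency <- c(primary = r44$C44, alternative = r44b$C44,
                                difference = r44$C44 - r44b$C44)
    report$velocities <- sound_velocities(es)
  }

  kap <- list()
  if (!is.null(spec) && !is.null(es)) {
    v <- report$velocities
    kap$kappa_min <- kappa_min(spec, v$vl, v$vt, inputs$rho_N, T_K)
  } else if (is.null(es)) {
    warning("no elastic input: kappa_min skipped")
  }
  if (!is.null(inputs[["ate"]])) {
    fit <- fit_ate_decay(inputs[["ate"]], window = cfg$ate_window_ns)
    report$ate_fit <- fit
    a <- inputs[["ate"]]
    c_cl_total <- c_cl * inputs$n_atoms * .KBOLTZ
    c_qm_total <- c_qm * inputs$n_atoms * .KBOLTZ
    kap$kappa_ate_classical <- kappa_ate(c_cl_total, a$Lx, a$A_cross,
                                         fit$tau * 1e-9)
    kap$kappa_ate_quantum <- kappa_ate(c_qm_total, a$Lx, a$A_cross,
                                       fit$tau * 1e-9)
  }
  report$kappa <- kap
  report
}

#' Crystallinity workflow over a series of configurations
#'
#' Per configuration: degree of crystallinity (P2 protocol), crystallite
#' census, and optionally the structure factor.
#'
#' @param confs list of [configuration()]s (non-empty).
#' @param config named list overriding `p2_min` (0.95), `r_neighbor` (0.5
#'   nm), `min_chains` (4), `lp` (3.4 nm), `monomer_spacing` (0.6 nm),
#'   `k_max` (nm^-1; `NULL` skips the structure factor),
#'   `max_per_shell` (128).
#' @return list with `d` (vector), `reports` (per-configuration
#'   [detect_crystallites()] results), `sk` (per-configuration structure
#'   factors or `NULL`), `config`.
#' @export
run_crystallinity_workflow <- function(confs, config = list()) {
  if (length(confs) == 0) stop("empty configuration list")
  cfg <- .merge_config(list(p2_min = 0.95, r_neighbor = 0.5, min_chains = 4,
                            lp = 3.4, monomer_spacing = 0.6, k_max = NULL,
                            max_per_shell = 128), config)
  reports <- lapply(confs, function(cf)
    detect_crystallites(cf, p2_min = cfg$p2_min, r_neighbor = cfg$r_neighbor,
                        min_chains = cfg$min_chains, lp = cfg$lp,
                        monomer_spacing = cfg$monomer_spacing))
  sk <- NULL
  if (!is.null(cfg$k_max))
    sk <- lapply(confs, structure_factor, k_max = cfg$k_max,
                 max_per_shell = cfg$max_per_shell)
  list(d = vapply(reports, function(r) r$d, numeric(1)),
       reports = reports, sk = sk, config = cfg)
}

#' Write a workflow report as JSON
#'
#' Serializes the scalar results and the effective configuration (large
#' array payloads such as the full spectrum are thinned to summaries).
#'
#' @param report result of [run_kappa_workflow()].
#' @param path output path.
#' @export
write_kappa_report <- function(report, path) {
  out <- report
  if (!is.null(out$spectrum))
    out$spectrum <- list(n_points = length(out$spectrum$nu),
                         nu_max_THz = max(out$spectrum$nu),
                         peak_THz = out$spectrum$nu[which.max(out$spectrum$g)])
  if (!is.null(out$elastic)) out$elastic <- unclass(out$elastic)
  if (!is.null(out$ate_fit)) out$ate_fit <- unclass(out$ate_fit)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
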