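# Thermal conductivity via (i) the minimum-thermal-conductivity model --
# each vibrational mode carries heat with a mean-free path of half its
# wavelength, Bose-Einstein weighted -- and (ii) the approach-to-equilibrium
# (ATE) transient: a hot/cold bipartition of the box relaxes microcanonically
# and the decay constant of DeltaT(t) yields kappa.

#' Minimum thermal conductivity from a vibrational spectrum
#'
#' kappa = rho_N h^2/(6 k_B T^2) * (v_l^2 + 2 v_t^2) *
#'         integral nu e^x/(e^x-1)^2 g(nu) d nu,   x = h nu / (k_B T),
#' by trapezoidal quadrature on the spectrum grid. The Bose-Einstein factor
#' is evaluated through 1/(4 sinh^2(x/2)) for stability, with the e^-x
#' asymptote beyond the exp-overflow threshold; the nu = 0 endpoint, a
#' measure-zero point where the integrand limit depends on the behaviour of
#' g near 0, contributes 0.
#'
#' @param spec a [vdos_spectrum()].
#' @param vl,vt longitudinal and transverse sound velocities (m/s).
#' @param rho_N atomic number density N/V (1/m^3).
#' @param T_K temperature (K), > 0.
#' @return kappa in W m^-1 K^-1.
#' @export
kappa_min <- function(spec, vl, vt, rho_N, T_K) {
  stopifnot(inherits(spec, "vdos_spectrum"))
  if (T_K <= 0) stop("temperature must be positive")
  if (vl < 0 || vt < 0 || rho_N <= 0) stop("vl, vt must be >= 0 and rho_N > 0")
  nu_T <- spec$nu                       # THz
  x <- .PLANCK * nu_T * 1e12 / (.KBOLTZ * T_K)
  bose <- numeric(length(x))
  big <- x > 700
  pos <- x > 0 & !big
  bose[big] <- exp(-x[big])
  bose[pos] <- 1 / (4 * sinh(x[pos] / 2)^2)
  integrand <- nu_T * bose * spec$g     # nu = 0 term stays 0
  I <- 1e12 * .trapz(nu_T, integrand)   # Hz-scale integral
  pref <- rho_N * .PLANCK^2 / (6 * .KBOLTZ * T_K^2)
  pref * (vl^2 + 2 * vt^2) * I
}

#' Classical (high-temperature) limit of the minimum-conductivity model
#'
#' kappa -> (rho_N k_B / 6) (v_l^2 + 2 v_t^2) * integral g(nu)/nu d nu,
#' valid when x = h nu / k_B T << 1 across the spectrum. Provided as an
#' independent check of [kappa_min()].
#'
#' @inheritParams kappa_min
#' @export
kappa_min_classical <- function(spec, vl, vt, rho_N) {
  nu <- spec$nu; g <- spec$g
  pos <- nu > 0
  I <- 1e-12 * .trapz(nu[pos], g[pos] / nu[pos])  # s
  (rho_N * .KBOLTZ / 6) * (vl^2 + 2 * vt^2) * I
}

#' Fit the exponential decay of an ATE series
#'
#' Nonlinear least squares of a * exp(-t/tau) on the windowed data. The
#' default window 0.02-0.20 ns excludes the fast initial transient caused by
#' intramolecular energy transfer.
#'
#' @param series an [ate_series()].
#' @param window fit window (ns), default c(0.02, 0.20).
#' @param offset if `TRUE`, fit a * exp(-t/tau) + b for non-ideal data
#'   (microcanonical decays relax to zero, so the default is `FALSE`).
#' @return object of class `"ate_fit"`: `tau` (ns), `tau_sd`, `amplitude`
#'   (K), `window`, and `offset` when fitted.
#' @export
fit_ate_decay <- function(series, window = c(0.02, 0.20), offset = FALSE) {
  stopifnot(inherits(series, "ate_series"))
  sel <- series$t >= window[1] & series$t <= window[2]
  if (sum(sel) < 10) stop("fewer than 10 points inside the fit window")
  t <- series$t[sel]; y <- series$dT[sel]
  if (mean(y > 0) < 0.5)
    stop("majority of DeltaT values in the window are non-positive")
  pos <- y > 0
  lf <- stats::lm.fit(cbind(1, t[pos]), log(y[pos]))
  tau0 <- -1 / min(lf$coefficients[2], -1e-8)
  a0 <- exp(lf$coefficients[1])
  fit <- tryCatch({
    if (offset)
      minpack.lm::nlsLM(y ~ a * exp(-t / tau) + b,
                        start = list(a = a0, tau = tau0, b = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ a * exp(-t / tau),
                        start = list(a = a0, tau = tau0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) stop("exponential fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  tau_sd <- tryCatch(sqrt(diag(stats::vcov(fit)))["tau"],
                     error = function(e) NA_real_)
  structure(list(tau = unname(cf["tau"]), tau_sd = unname(tau_sd),
                 amplitude = unname(cf["a"]),
                 offset = if (offset) unname(cf["b"]) else NULL,
                 window = window),
            class = "ate_fit")
}

#' Thermal conductivity from the ATE decay constant
#'
#' kappa = (1/(4 pi^2)) * c_total * L_x / (A_cross * tau). `c_total` is the
#' EXTENSIVE heat capacity of the sample (a per-atom value in k_B must be
#' multiplied by N k_B first); only then does the expression carry
#' W m^-1 K^-1.
#'
#' @param c_total extensive heat capacity (J/K).
#' @param Lx box length along the transport axis (m).
#' @param A_cross cross-sectional area (m^2).
#' @param tau decay constant (s).
#' @return kappa in W m^-1 K^-1.
#' @export
kappa_ate <- function(c_total, Lx, A_cross, tau) {
  if (any(c(c_total, Lx, A_cross, tau) <= 0))
    stop("c_total, Lx, A_cross and tau must all be positive")
  c_total * Lx / (4 * pi^2 * A_cross * tau)
}

#' Conductivities normalized to the amorphous reference
#'
#' @param d degrees of crystallinity.
#' @param kappa conductivities at each `d` (W m^-1 K^-1).
#' @param kappa_amorphous amorphous reference conductivity (> 0).
#' @param kappa_sd,kappa_amorphous_sd optional standard deviations; when
#'   both present the ratio sd is propagated in quadrature.
#' @return data.frame with columns `d`, `ratio`, `ratio_sd`.
#' @export
kappa_ratio_vs_crystallinity <- function(d, kappa, kappa_amorphous,
                                         kappa_sd = NULL,
                                         kappa_amorphous_sd = NULL) {
  if (kappa_amorphous <= 0) stop("kappa_amorphous must be positive")
  if (length(d) != length(kappa)) stop("d and kappa must match in length")
  ratio <- kappa / kappa_amorphous
  ratio_sd <- rep(NA_real_, length(ratio))
  if (!is.null(kappa_sd)) {
    rel0 <- if (!is.null(kappa_amorphous_sd)) kappa_amorphous_sd / kappa_amorphous else 0
    ratio_sd <- ratio * sqrt((kappa_sd / kappa)^2 + rel0^2)
  }
  data.frame(d = d, ratio = ratio, ratio_sd = ratio_sd)
}
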