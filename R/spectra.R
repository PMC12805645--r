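# Mass-weighted velocity autocorrelation and the vibrational density of
# states. The VDOS is the cosine transform of the normalized VACF,
#   g(nu) = (1/A) * integral_0^inf cos(2 pi nu t) psi(t)/psi(0) dt,
# with A fixed so that the trapezoidal integral of g over nu is 1.

#' Normalized vibrational density of states
#'
#' @param nu frequency grid (THz), strictly increasing, starting at 0.
#' @param g density per THz, nonnegative; renormalized on construction so
#'   that the trapezoidal integral over `nu` equals 1.
#' @return object of class `"vdos_spectrum"`.
#' @export
vdos_spectrum <- function(nu, g) {
  if (length(nu) != length(g)) stop("nu and g must have the same length")
  if (length(nu) < 2) stop("spectrum needs at least two grid points")
  if (any(diff(nu) <= 0)) stop("frequency grid must be strictly increasing")
  if (abs(nu[1]) > 1e-12) stop("frequency grid must start at 0")
  if (any(g < 0)) stop("density must be nonnegative")
  tot <- .trapz(nu, g)
  if (tot <= 0) stop("spectrum has zero integral; cannot normalize")
  g <- g / tot
  stopifnot(abs(.trapz(nu, g) - 1) < 1e-6)
  structure(list(nu = as.numeric(nu), g = as.numeric(g)),
            class = "vdos_spectrum")
}

#' @export
print.vdos_spectrum <- function(x, ...) {
  cat(sprintf("vdos_spectrum: %d points, 0-%g THz, integral = %.6f\n",
              length(x$nu), max(x$nu), .trapz(x$nu, x$g)))
  invisible(x)
}

#' Narrow (Einstein-like) single-mode spectrum
#'
#' Triangular spike of half-width `dnu` centred at `nu0`, normalized to unit
#' integral. Useful as a numerical stand-in for a delta-function mode when
#' checking closed-form Einstein-model expressions.
#'
#' @param nu0 mode frequency (THz), > 0.
#' @param dnu half-width of the spike (THz), small compared to `nu0`.
#' @export
einstein_spectrum <- function(nu0, dnu = 1e-4) {
  stopifnot(nu0 > 0, dnu > 0, dnu < nu0)
  nu <- c(0, nu0 - dnu, nu0, nu0 + dnu)
  g <- c(0, 0, 1 / dnu, 0)
  vdos_spectrum(nu, g)
}

#' Mass-weighted velocity autocorrelation function
#'
#' psi(lag) = < sum_i m_i v_i(t0 + lag) . v_i(t0) >, averaged over evenly
#' spaced time origins t0.
#'
#' @param traj a [trajectory()].
#' @param max_lag maximum lag (ps); default half the trajectory duration.
#' @param n_origins number of time origins (default: one origin every 10
#'   output intervals across the admissible range).
#' @return object of class `"vacf"` with fields `t` (lag grid, ps) and
#'   `psi` (amu nm^2/ps^2).
#' @export
mass_weighted_vacf <- function(traj, max_lag = NULL, n_origins = NULL) {
  dt <- traj$dt_out
  dur <- trajectory_duration(traj)
  if (is.null(max_lag)) max_lag <- dur / 2
  if (max_lag > dur + 1e-12)
    stop("max_lag (", max_lag, " ps) exceeds trajectory duration (", dur, " ps)")
  n_lag <- floor(max_lag / dt + 1e-9)
  last_origin <- traj$n_frames - n_lag          # origins 1..last_origin
  if (last_origin < 1) stop("lag grid exceeds available frames")
  if (is.null(n_origins)) n_origins <- max(1L, floor((last_origin - 1) / 10) + 1L)
  if (n_origins < 1) stop("n_origins must be >= 1")
  origins <- unique(round(seq(1, last_origin, length.out = min(n_origins, last_origin))))
  V <- matrix(traj$velocities, traj$n_frames, traj$n_atoms * 3)
  w <- rep(traj$masses, times = 3)
  psi <- numeric(n_lag + 1)
  V0 <- V[origins, , drop = FALSE]
  for (l in 0:n_lag) {
    Vl <- V[origins + l, , drop = FALSE]
    psi[l + 1] <- mean((V0 * Vl) %*% w)
  }
  structure(list(t = (0:n_lag) * dt, psi = psi, n_origins = length(origins)),
            class = "vacf")
}

#' Vibrational density of states from a VACF
#'
#' Type-I discrete cosine transform (trapezoid end weights) of
#' `psi(t)/psi(0)`, optionally Hann-windowed to suppress truncation ringing
#' on short records, clipped at zero from below and renormalized to unit
#' integral. The frequency grid spans 0 to the Nyquist frequency
#' `1/(2*dlag)`.
#'
#' @param vacf a `"vacf"` object with a uniform lag grid.
#' @param window `"hann"` (default) or `"none"`.
#' @return a [vdos_spectrum()].
#' @export
vdos_from_vacf <- function(vacf, window = c("hann", "none")) {
  window <- match.arg(window)
  t <- vacf$t; psi <- vacf$psi
  M <- length(t) - 1L
  if (M < 2) stop("VACF too short for a spectrum")
  dt <- t[2] - t[1]
  if (max(abs(diff(t) - dt)) > 1e-9 * dt) stop("VACF lag grid must be uniform")
  if (!is.finite(psi[1]) || psi[1] <= 0)
    stop("psi(0) <= 0: trajectory carries no kinetic energy")
  y <- psi / psi[1]
  if (window == "hann") y <- y * (0.5 * (1 + cos(pi * (0:M) / M)))
  # DCT-I with trapezoid end weights via FFT of the even extension
  z <- c(y, rev(y[2:M]))
  g_raw <- dt * Re(stats::fft(z))[1:(M + 1)] / 2
  nu <- (0:M) / (2 * M * dt)    # THz, since dt is in ps
  g_raw[g_raw < 0] <- 0
  vdos_spectrum(nu, g_raw)
}

#' Full VDOS pipeline from a trajectory
#'
#' Composes [mass_weighted_vacf()] and [vdos_from_vacf()]. The defaults
#' mirror a 10 ps sampling window at a 5e-4 ps output interval (Nyquist
#' 1000 THz); the lag grid spans half the trajectory so the remaining half
#' provides time-origin averaging.
#'
#' @inheritParams mass_weighted_vacf
#' @inheritParams vdos_from_vacf
#' @param min_duration minimum accepted trajectory duration (ps).
#' @return a [vdos_spectrum()].
#' @export
vdos_pipeline <- function(traj, max_lag = NULL, n_origins = NULL,
                          window = "hann", min_duration = 10) {
  if (trajectory_duration(traj) + 1e-9 < min_duration)
    stop("trajectory shorter than ", min_duration,
         " ps; lower min_duration to override")
  vdos_from_vacf(mass_weighted_vacf(traj, max_lag, n_origins), window = window)
}

#' Write a spectrum as CSV (nu_THz, g_per_THz)
#' @param spec a [vdos_spectrum()].
#' @param path output path.
#' @export
write_spectrum <- function(spec, path) {
  utils::write.csv(format(data.frame(nu_THz = spec$nu, g_per_THz = spec$g),
                          digits = 12, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum from CSV
#' @param path CSV with columns `nu_THz, g_per_THz`.
#' @export
read_spectrum <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("nu_THz", "g_per_THz") %in% names(d)))
    stop("spectrum CSV must have columns nu_THz, g_per_THz")
  vdos_spectrum(d$nu_THz, d$g_per_THz)
}
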