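# Heat capacity: classical estimate by central difference of the enthalpy,
# quantum correction by Bose-Einstein weighting of the vibrational spectrum,
# and the glass transition from the specific-volume crossover.

# x^2 e^x / (e^x - 1)^2, the Einstein heat-capacity factor, evaluated
# stably: equals x^2 / (4 sinh^2(x/2)); -> 1 as x -> 0, -> x^2 e^-x at
# large x (exp overflow threshold 700).
.einstein_factor <- function(x) {
  out <- numeric(length(x))
  tiny <- x < 1e-10
  big <- x > 700
  mid <- !tiny & !big
  out[tiny] <- 1
  out[big] <- x[big]^2 * exp(-x[big])
  out[mid] <- (x[mid] / (2 * sinh(x[mid] / 2)))^2
  out
}

#' Classical heat capacity by central difference
#'
#' c_cl(T) = {H(T + dT) - H(T - dT)} / (2 dT), per atom, reported in units
#' of k_B. `dT` defaults to the grid step of the enthalpy series, which must
#' be uniform so the bracketing points exist for every interior T.
#'
#' @param H a [thermo_series()] of total enthalpy (J) on a uniform grid.
#' @param n_atoms number of atoms, for the per-atom normalization.
#' @param dT half-width of the central difference (K); must be a multiple of
#'   the grid step.
#' @return a [thermo_series()] of c_cl in k_B per atom at the interior
#'   temperatures.
#' @export
classical_heat_capacity <- function(H, n_atoms, dT = NULL) {
  stopifnot(inherits(H, "thermo_series"), n_atoms >= 1)
  step <- diff(H$T)
  if (max(abs(step - step[1])) > 1e-8 * step[1])
    stop("enthalpy grid must be uniform for the central difference")
  h <- step[1]
  if (is.null(dT)) dT <- h
  k <- round(dT / h)
  if (abs(k * h - dT) > 1e-8 * h || k < 1)
    stop("dT must be a positive multiple of the grid step (", h, " K)")
  n <- length(H$T)
  idx <- (1 + k):(n - k)
  if (length(idx) < 1)
    stop("no temperature has both bracketing points T +/- ", dT, " K")
  c_cl <- (H$y[idx + k] - H$y[idx - k]) / (2 * dT) / n_atoms / .KBOLTZ
  thermo_series(H$T[idx], c_cl, label = "heat_capacity")
}

#' Quantum correction to the heat capacity
#'
#' Difference between the classical and quantum per-mode heat capacities,
#' Delta_c / k_B = integral { 1 - x^2 e^x/(e^x-1)^2 } g(nu) d nu with
#' x = h nu / k_B T, by trapezoidal quadrature on the spectrum grid. The
#' integrand vanishes at x = 0 (classical limit) and approaches 1 for
#' frozen high-frequency modes, so 0 <= Delta_c <= 1 k_B for any normalized
#' spectrum.
#'
#' @param spec a [vdos_spectrum()].
#' @param T_K temperature (K), > 0.
#' @return Delta_c in units of k_B (per vibrational mode; multiply by 3 for
#'   a per-atom figure when the classical reference is 3 k_B/atom).
#' @export
delta_c_quantum <- function(spec, T_K) {
  stopifnot(inherits(spec, "vdos_spectrum"))
  if (!is.numeric(T_K) || T_K <= 0) stop("temperature must be positive")
  x <- .PLANCK * spec$nu * 1e12 / (.KBOLTZ * T_K)
  .trapz(spec$nu, (1 - .einstein_factor(x)) * spec$g)
}

#' Quantum-corrected heat capacity
#'
#' c = c_cl - Delta_c, both in k_B per atom (or per mode; the two inputs
#' must share a basis).
#'
#' @param c_cl classical heat capacity: a [thermo_series()] (label
#'   `"heat_capacity"`) or a numeric vector in k_B.
#' @param delta_c quantum correction(s) in k_B, scalar or matching length.
#' @return object of class `"heat_capacity_result"` with fields `T`, `c_cl`,
#'   `delta_c`, `c_qm` (all in k_B), or a numeric vector when `c_cl` is
#'   numeric.
#' @export
quantum_heat_capacity <- function(c_cl, delta_c) {
  if (inherits(c_cl, "thermo_series")) {
    if (!length(delta_c) %in% c(1L, length(c_cl$y)))
      stop("delta_c length must be 1 or match the series")
    structure(list(T = c_cl$T, c_cl = c_cl$y, delta_c = rep(delta_c, length.out = length(c_cl$y)),
                   c_qm = c_cl$y - delta_c),
              class = "heat_capacity_result")
  } else {
    if (!length(delta_c) %in% c(1L, length(c_cl)))
      stop("delta_c length must be 1 or match c_cl")
    c_cl - delta_c
  }
}

#' Convert a per-atom heat capacity from k_B units to J/(kg K)
#'
#' @param c_kB heat capacity in k_B per atom.
#' @param mean_atomic_mass_amu average atomic mass (amu).
#' @export
heat_capacity_si <- function(c_kB, mean_atomic_mass_amu) {
  c_kB * .KBOLTZ / (mean_atomic_mass_amu * .AMU)
}

#' Glass transition from the specific-volume crossover
#'
#' Fits two straight lines to v(T), with the split searched exhaustively
#' over interior grid intervals (each segment keeps at least `min_points`
#' points), and takes Tg as the intersection of the two fitted lines. If the
#' two-segment fit is statistically indistinguishable from a single line
#' (F-ratio below `f_min`, or the data are exactly collinear), the result is
#' flagged `crossover = FALSE`.
#'
#' @param v a [thermo_series()] of specific volume vs temperature.
#' @param min_points minimum points per segment (default 3).
#' @param f_min F-ratio threshold for accepting the broken fit over a single
#'   line (default: the 99% quantile of the reference F distribution).
#' @return object of class `"tg_result"`: `Tg` (K, or NA), `slopes`
#'   (glass, melt), `sse`, `crossover` flag.
#' @export
tg_from_specific_volume <- function(v, min_points = 3, f_min = NULL) {
  stopifnot(inherits(v, "thermo_series"))
  n <- length(v$T)
  if (n < 2 * min_points) stop("need at least ", 2 * min_points, " points")
  x <- v$T; y <- v$y
  sse_line <- function(i) {
    f <- stats::lm.fit(cbind(1, x[i]), y[i]); sum(f$residuals^2)
  }
  fit_line <- function(i) stats::lm.fit(cbind(1, x[i]), y[i])$coefficients
  best <- list(sse = Inf, split = NA)
  for (s in min_points:(n - min_points)) {
    sse <- sse_line(1:s) + sse_line((s + 1):n)
    if (sse < best$sse) best <- list(sse = sse, split = s)
  }
  s <- best$split
  cf1 <- fit_line(1:s); cf2 <- fit_line((s + 1):n)
  sse1 <- sum(stats::lm.fit(cbind(1, x), y)$residuals^2)  # single line
  scale <- sum((y - mean(y))^2)
  if (is.null(f_min)) f_min <- stats::qf(0.99, 2, max(n - 4, 1))
  f_ratio <- if (best$sse > 0) ((sse1 - best$sse) / 2) / (best$sse / max(n - 4, 1)) else Inf
  collinear <- sse1 <= 1e-20 * max(scale, 1e-300)
  no_cross <- collinear || (is.finite(f_ratio) && f_ratio < f_min) ||
    abs(cf2[2] - cf1[2]) < 1e-12 * max(abs(cf1[2]), abs(cf2[2]), 1e-300)
  if (no_cross)
    return(structure(list(Tg = NA_real_, slopes = c(glass = unname(cf1[2]),
                                                    melt = unname(cf2[2])),
                          sse = best$sse, crossover = FALSE),
                     class = "tg_result"))
  Tg <- (cf1[1] - cf2[1]) / (cf2[2] - cf1[2])
  if (!is.finite(Tg) || Tg <= min(x) || Tg >= max(x))
    return(structure(list(Tg = NA_real_, slopes = c(glass = unname(cf1[2]),
                                                    melt = unname(cf2[2])),
                          sse = best$sse, crossover = FALSE),
                     class = "tg_result"))
  structure(list(Tg = unname(Tg),
                 slopes = c(glass = unname(cf1[2]), melt = unname(cf2[2])),
                 sse = best$sse, crossover = TRUE),
            class = "tg_result")
}

#' @export
print.tg_result <- function(x, ...) {
  if (x$crossover)
    cat(sprintf("Tg = %.1f K (slopes %.3e -> %.3e, sse %.3e)\n",
                x$Tg, x$slopes[1], x$slopes[2], x$sse))
  else cat("no crossover detected\n")
  invisible(x)
}
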