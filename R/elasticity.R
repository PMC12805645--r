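# Elastic constants from finite-strain stress responses, and the sound
# velocities that feed the minimum-thermal-conductivity model.
#
# Strain protocols for a cubic reference box of side L:
#   volume-conserving shear:  Lx = L(1+eps), Ly = L/(1+eps), Lz = L
#   uniaxial (+/-):           Lx = L(1 +/- eps), Ly = Lz = L
# Estimators (tensile stress convention; flip the sign of an MD pressure
# tensor before use):
#   C44 = {sxx(shear +eps) - sxx(0)} / (2 eps)
#       = -{syy(shear -eps) - syy(0)} / (2 eps)   (consistency diagnostic)
#   C11 = {sxx(+eps) - sxx(-eps)} / (2 eps)
#   C12 = {syy(+eps) - syy(-eps)} / (2 eps)

#' Box lengths of a strained configuration
#'
#' @param L reference cubic box length (nm).
#' @param eps strain magnitude (> 0 for the strained protocols); values
#'   above 1e-2 trigger a warning (linear-response regime assumed).
#' @param kind `"shear_volume_conserving"`, `"uniaxial_plus"`,
#'   `"uniaxial_minus"`, or `"reference"`.
#' @return numeric c(Lx, Ly, Lz).
#' @export
strained_box <- function(L, eps,
                         kind = c("shear_volume_conserving", "uniaxial_plus",
                                  "uniaxial_minus", "reference")) {
  kind <- match.arg(kind)
  stopifnot(L > 0, eps >= 0)
  if (eps > 1e-2) warning("eps = ", eps, " is outside the linear-response regime")
  switch(kind,
         shear_volume_conserving = c(L * (1 + eps), L / (1 + eps), L),
         uniaxial_plus = c(L * (1 + eps), L, L),
         uniaxial_minus = c(L * (1 - eps), L, L),
         reference = c(L, L, L))
}

#' Stress record for one strain protocol
#'
#' @param t time grid (ps).
#' @param sxx,syy,szz diagonal stress components (GPa).
#' @param protocol protocol tag (see [strained_box()] plus
#'   `"shear_minus"` for the negatively sheared state).
#' @return object of class `"stress_record"` (a data.frame).
#' @export
stress_record <- function(t, sxx, syy, szz, protocol) {
  if (any(!is.finite(c(sxx, syy, szz)))) stop("stress values must be finite")
  structure(data.frame(t_ps = t, sxx_GPa = sxx, syy_GPa = syy, szz_GPa = szz,
                       protocol = protocol),
            class = c("stress_record", "data.frame"))
}

.window_rows <- function(rec, window) {
  sel <- rec$t_ps >= window[1] & rec$t_ps <= window[2]
  if (sum(sel) < 5) stop("averaging window [", window[1], ", ", window[2],
                         "] ps covers fewer than 5 samples")
  which(sel)
}

.block_sd <- function(x, n_blocks = 5) {
  n <- length(x)
  b <- split(x, cut(seq_len(n), n_blocks, labels = FALSE))
  stats::sd(vapply(b, mean, numeric(1)))
}

#' Shear modulus C44 from sheared and reference stress series
#'
#' Time average over `window` of the instantaneous estimator; the standard
#' deviation comes from 5 block averages of the window. The primary
#' estimator uses sxx of the positively sheared state; the alternative uses
#' syy of the negatively sheared state, and the difference between the two
#' serves as a consistency diagnostic.
#'
#' @param sigma_sheared [stress_record()] of the sheared state.
#' @param sigma_ref [stress_record()] of the unstrained reference.
#' @param eps strain magnitude.
#' @param window averaging window (ps), default c(50, 150); c(50, 100)
#'   is a common alternative.
#' @param method `"sxx_plus"` (default) or `"syy_minus"`.
#' @return list with `C44` (GPa), `sd`, `method`, `window`.
#' @export
c44_from_stress <- function(sigma_sheared, sigma_ref, eps,
                            window = c(50, 150),
                            method = c("sxx_plus", "syy_minus")) {
  method <- match.arg(method)
  stopifnot(eps > 0)
  i1 <- .window_rows(sigma_sheared, window)
  i0 <- .window_rows(sigma_ref, window)
  if (length(i1) != length(i0))
    stop("sheared and reference series sample the window differently")
  inst <- if (method == "sxx_plus")
    (sigma_sheared$sxx_GPa[i1] - sigma_ref$sxx_GPa[i0]) / (2 * eps)
  else
    -(sigma_sheared$syy_GPa[i1] - sigma_ref$syy_GPa[i0]) / (2 * eps)
  list(C44 = mean(inst), sd = .block_sd(inst), method = method, window = window)
}

#' C11 and C12 from oppositely strained uniaxial states
#'
#' C11 = <sxx(+eps) - sxx(-eps)>/(2 eps);
#' C12 = <syy(+eps) - syy(-eps)>/(2 eps). Taking the difference between the
#' two strained states cancels the (noisy) unstrained baseline.
#'
#' @param sigma_plus,sigma_minus [stress_record()]s of the +eps / -eps
#'   uniaxial states.
#' @inheritParams c44_from_stress
#' @return list with `C11`, `C12` (GPa), `sd_C11`, `sd_C12`, `window`.
#' @export
c11_c12_from_stress <- function(sigma_plus, sigma_minus, eps,
                                window = c(50, 150)) {
  stopifnot(eps > 0)
  ip <- .window_rows(sigma_plus, window)
  im <- .window_rows(sigma_minus, window)
  if (length(ip) != length(im))
    stop("strained series sample the window differently")
  inst11 <- (sigma_plus$sxx_GPa[ip] - sigma_minus$sxx_GPa[im]) / (2 * eps)
  inst12 <- (sigma_plus$syy_GPa[ip] - sigma_minus$syy_GPa[im]) / (2 * eps)
  list(C11 = mean(inst11), C12 = mean(inst12),
       sd_C11 = .block_sd(inst11), sd_C12 = .block_sd(inst12), window = window)
}

#' Elastic-constant set at one temperature
#'
#' @param T_K temperature (K).
#' @param C11,C12,C44 elastic constants (GPa).
#' @param sd_C11,sd_C12,sd_C44 standard deviations (GPa).
#' @param rho_m mass density (kg/m^3), > 0.
#' @return object of class `"elastic_set"`. Physically valid sets have
#'   C11 >= C44 >= 0; violations warn but are kept.
#' @export
elastic_set <- function(T_K, C11, C12, C44, rho_m,
                        sd_C11 = NA, sd_C12 = NA, sd_C44 = NA) {
  if (rho_m <= 0) stop("rho_m must be positive")
  if (C44 < 0 || C11 < C44)
    warning("elastic set violates C11 >= C44 >= 0; retained with warning")
  structure(list(T = T_K, C11 = C11, C12 = C12, C44 = C44, rho_m = rho_m,
                 sd_C11 = sd_C11, sd_C12 = sd_C12, sd_C44 = sd_C44),
            class = "elastic_set")
}

#' Longitudinal and transverse sound velocities
#'
#' v_l = sqrt(C11/rho_m), v_t = sqrt(C44/rho_m).
#'
#' @param es an [elastic_set()] (C11, C44 in GPa; rho_m in kg/m^3).
#' @return list with `vl`, `vt` in m/s.
#' @export
sound_velocities <- function(es) {
  stopifnot(inherits(es, "elastic_set"))
  if (es$C11 < 0 || es$C44 < 0) stop("negative modulus: sound velocity undefined")
  list(vl = sqrt(es$C11 * 1e9 / es$rho_m), vt = sqrt(es$C44 * 1e9 / es$rho_m))
}

#' Poisson ratio from C11 and C44
#'
#' Inverts C11 = 2 C44 (1 - nu_p)/(1 - 2 nu_p):
#' nu_p = (C11 - 2 C44) / (2 C11 - 2 C44).
#'
#' @param C11,C44 elastic constants (GPa), with C11 > C44 > 0.
#' @return Poisson ratio nu_p.
#' @export
poisson_ratio_from_moduli <- function(C11, C44) {
  if (!(C11 > C44 && C44 > 0))
    stop("relation requires C11 > C44 > 0")
  (C11 - 2 * C44) / (2 * (C11 - C44))
}

#' C11 implied by C44 and a Poisson ratio
#'
#' Forward form of the relation inverted by [poisson_ratio_from_moduli()].
#' @param C44 shear modulus (GPa).
#' @param nu_p Poisson ratio in (0, 0.5).
#' @export
c11_from_poisson <- function(C44, nu_p) {
  stopifnot(nu_p >= 0, nu_p < 0.5)
  2 * C44 * (1 - nu_p) / (1 - 2 * nu_p)
}
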