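# Independent oracles used across the suite. These deliberately use naive
# algorithms (double loops, closed forms, adaptive quadrature) so they stay
# independent of the implementation paths they check.

PLANCK <- 6.62607015e-34
KBOLTZ <- 1.380649e-23
AMU <- 1.66053906660e-27

# brute-force mass-weighted VACF: explicit double loop over origins and atoms
bf_vacf <- function(traj, n_lag, origins) {
  psi <- numeric(n_lag + 1)
  for (l in 0:n_lag) {
    acc <- 0
    for (o in origins) {
      s <- 0
      for (i in seq_len(traj$n_atoms))
        s <- s + traj$masses[i] *
          sum(traj$velocities[o + l, i, ] * traj$velocities[o, i, ])
      acc <- acc + s
    }
    psi[l + 1] <- acc / length(origins)
  }
  psi
}

# brute-force O(M^2) cosine-sum transform with trapezoid end weights
bf_cosine_transform <- function(y, dt) {
  M <- length(y) - 1L
  w <- c(0.5, rep(1, M - 1), 0.5)
  vapply(0:M, function(k)
    dt * sum(w * y * cos(pi * (0:M) * k / M)), numeric(1))
}

# closed-form Einstein-model quantities at dimensionless x = h nu / kB T
einstein_c <- function(x) x^2 * exp(x) / (exp(x) - 1)^2
einstein_delta_c <- function(x) 1 - einstein_c(x)

# one-line Einstein evaluation of the minimum-conductivity integral
einstein_kappa_min <- function(nu0_THz, vl, vt, rho_N, T_K) {
  x <- PLANCK * nu0_THz * 1e12 / (KBOLTZ * T_K)
  rho_N * PLANCK^2 / (6 * KBOLTZ * T_K^2) * (vl^2 + 2 * vt^2) *
    nu0_THz * 1e12 * exp(x) / (exp(x) - 1)^2
}

# a smooth analytic normalized spectrum on [0, nu_max]: g(nu) ~ nu^2 (nu_max - nu)
smooth_g <- local({
  nu_max <- 40
  norm <- nu_max^4 / 12
  function(nu) ifelse(nu >= 0 & nu <= nu_max, nu^2 * (nu_max - nu) / norm, 0)
})
smooth_g_numax <- 40

# mean-squared end-to-end distance of a discrete chain with bond correlation g
discrete_wlc_r2 <- function(b, g, n_bonds) {
  b^2 * (n_bonds * (1 + g) / (1 - g) -
           2 * g * (1 - g^n_bonds) / (1 - g)^2)
}

# rotate a configuration rigidly about an axis (for invariance checks)
rotate_configuration <- function(conf, axis = c(0, 0, 1), angle = pi / 7,
                                 shift = c(0, 0, 0)) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) * ca + sa * K + (1 - ca) * (a %o% a)
  out <- conf
  out$sites <- sweep(conf$sites %*% t(R), 2, shift, `+`)
  out
}
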