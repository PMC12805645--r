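---
title: "Heat-transport analysis of dense polysaccharide melts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat-transport analysis of dense polysaccharide melts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celluheat)
```

`celluheat` post-processes molecular-dynamics output for heat-flow studies
of dense, solvent-free cellulose-like polymers. The MD engine itself is out
of scope: the package starts from velocity trajectories, stress and
enthalpy series, and chain configurations, and ends at thermal
conductivities, elastic constants, crystallinity and chain statistics.
Because every analysis stage also has a seeded synthetic generator with
known ground truth, the whole pipeline is testable as a closed loop.

## Vibrational density of states

The mass-weighted velocity autocorrelation function
$\psi(t) = \sum_i m_i \langle \vec v_i(t)\cdot \vec v_i(0)\rangle$
is averaged over evenly spaced time origins
(`mass_weighted_vacf()`; origin spacing defaults to 10 output intervals).
The vibrational density of states is its Fourier cosine transform,

$$ g(\nu) = \frac{1}{A}\int_0^\infty \cos(2\pi\nu t)\,
   \frac{\psi(t)}{\psi(0)}\,dt, $$

with $A$ fixed so that $\int g\,d\nu = 1$ (asserted post hoc to $10^{-6}$).
Numerical choices, all of which only matter for finite records:

* **Normalization by $\psi(0)$.** The transform is applied to
  $\psi(t)/\psi(0)$; any overall constant is absorbed by $A$, so this
  choice is a convention, not a physical assumption.
* **Quadrature.** A type-I discrete cosine transform with trapezoid end
  weights, evaluated through an FFT of the even extension; it mirrors the
  printed integral exactly and is checked in the tests against a literal
  $O(n^2)$ cosine sum to $10^{-8}$ relative.
* **Hann window** on $\psi(t)$ by default (disable with
  `window = "none"`): a 10 ps record truncates $\psi$ mid-oscillation and
  the window suppresses the resulting ringing. With the window, a single
  mode's weight spreads into the $\pm 1$ neighbouring bins, which is why
  weight-recovery checks integrate over a few bins around a peak.
* **Clipping.** Finite records can produce small negative transform
  values; a density must be nonnegative, so negatives are clipped to zero
  before renormalization.

The frequency grid runs from 0 to the Nyquist frequency $1/(2\Delta t)$;
at the conventional 5×10⁻⁴ ps output interval that is 1000 THz.

## Heat capacity and its quantum correction

The classical heat capacity is the central difference of the enthalpy,
$c^{\mathrm{cl}}(T) = \{H(T+\Delta T) - H(T-\Delta T)\}/2\Delta T$,
per atom (`classical_heat_capacity()`). $\Delta T$ defaults to the grid
step of the supplied series — a typical cooling protocol stores enthalpy
every 20 K — and is configurable to any multiple of it.

Classical dynamics excites every mode, but at ambient temperature modes
well above $k_B T/h$ (6.25 THz at 300 K, `thermal_frequency()`) are
quantum-mechanically frozen. The correction

$$ \frac{\Delta c(T)}{k_B} = \int_0^\infty
   \left\{ 1 - \frac{x^2 e^x}{(e^x-1)^2} \right\} g(\nu)\, d\nu,
   \qquad x = \frac{h\nu}{k_B T}, $$

is evaluated by trapezoidal quadrature on the spectrum grid
(`delta_c_quantum()`), and `quantum_heat_capacity()` forms
$c = c^{\mathrm{cl}} - \Delta c$. Numerics: the bracketed factor is
computed as $1 - x^2/(4\sinh^2(x/2))$, which is stable down to $x=0$
(where it vanishes — the classical limit) and switches to the asymptote
$1 - x^2 e^{-x}$ beyond $x = 700$ to avoid overflow. For a normalized
spectrum the integrand lies in $[0,1]$, so $0 \le \Delta c \le 1\,k_B$:
**the correction is per vibrational mode**. An atom carries three modes,
so applying the correction to a per-atom classical value requires the
factor 3; `run_kappa_workflow()` exposes this as `modes_per_atom` with
default 3. The subtraction itself is kept as the printed one-line formula
so the two bases can also be matched per mode.

## Thermal conductivity

Two estimators are provided.

**Minimum-conductivity model** (`kappa_min()`): every mode transports
heat with a mean-free path of half its wavelength (lifetime $1/2\nu$),
giving

$$ \kappa(T) = \frac{\rho_N h^2}{6 k_B T^2}\,(v_l^2 + 2 v_t^2)
   \int_0^\infty \nu\, \frac{e^{x}}{(e^{x}-1)^2}\, g(\nu)\, d\nu . $$

The velocity factor $(v_l^2 + 2v_t^2)$ is the isotropic sum over one
longitudinal and two transverse branches; dimensional analysis of the
prefactor requires squared velocities for $\kappa$ to come out in
W m⁻¹ K⁻¹, and the same form follows from the kinetic expression
$\frac13 c v^2 \tau$ with $\tau = 1/2\nu$. The Bose–Einstein factor uses
the same $\sinh$ form as above. At $\nu = 0$ the integrand's limit
depends on how $g$ approaches zero; the endpoint is a measure-zero point
of the trapezoid rule and contributes nothing (tests confirm grid-halving
changes $\kappa$ by under 0.1 %). In the classical limit
($x_{\max} < 0.01$) the model reduces to
$(\rho_N k_B/6)(v_l^2+2v_t^2)\int g/\nu\,d\nu$, provided independently as
`kappa_min_classical()` for cross-checking. Frequency-independent sound
velocities are assumed, a low-temperature approximation.

**Approach-to-equilibrium** (`fit_ate_decay()` + `kappa_ate()`): a hot
and a cold half of the box relax microcanonically; the temperature
difference decays as $\Delta T(t) \propto e^{-t/\tau}$ after an initial
fast transient caused by intramolecular energy transfer. The default fit
window 0.02–0.20 ns excludes that transient; the exponential has no
offset term by default because a microcanonical decay relaxes to zero
(an offset can be enabled for non-ideal data). Then

$$ \kappa(T) = \frac{1}{4\pi^2}\, \frac{c(T)\, L_x(T)}{A(T)\, \tau(T)}, $$

where $c$ is the **extensive** heat capacity (J/K): only then does
$c L_x/(A\tau)$ carry W m⁻¹ K⁻¹. A per-atom value in $k_B$ must be
multiplied by $N k_B$; the workflow does this explicitly. Using the
classical versus the quantum-corrected $c$ gives the two ATE variants,
and the quantum one is necessarily lower whenever the spectrum has
frozen weight.

## Elastic constants and sound velocities

Small strains ($\varepsilon = 10^{-3}$ by default; warnings above
$10^{-2}$) are applied to a cubic box of side $L$
(`strained_box()`): a volume-conserving shear
$L_x = L(1+\varepsilon),\ L_y = L/(1+\varepsilon),\ L_z = L$ and uniaxial
stretches $L_x = L(1\pm\varepsilon)$. The estimators difference stress
records so the unstrained baseline cancels:

* $C_{44} = \{\sigma_{xx}(+\varepsilon) - \sigma_{xx}(0)\}/2\varepsilon$,
  with the alternative
  $-\{\sigma_{yy}(-\varepsilon) - \sigma_{yy}(0)\}/2\varepsilon$
  computed as a consistency diagnostic (`c44_from_stress()`);
* $C_{11},\ C_{12}$ from the $\sigma_{xx}$ and $\sigma_{yy}$ differences
  of the two opposite uniaxial states (`c11_c12_from_stress()`).

Averaging uses the 50–150 ps window by default (a 50–100 ps window is a
common alternative; pass `window = c(50, 100)`), and the quoted
uncertainty is the standard deviation of five sub-window block averages.
The stress convention is tensile (positive under extension); readers of
MD pressure tensors must flip the sign. Sound velocities follow as
$v_l = \sqrt{C_{11}/\rho_m}$, $v_t = \sqrt{C_{44}/\rho_m}$, and the
Poisson ratio from
$C_{11} = 2C_{44}(1-\nu_p)/(1-2\nu_p)$, inverted exactly
(`poisson_ratio_from_moduli()`).

## Structure factor

`structure_factor()` evaluates
$S(k) = \langle |\sum_i e^{i\vec k\cdot\vec R_i}|^2 \rangle / N_0$ on the
lattice of box-commensurate wave vectors
$\vec k = 2\pi(n_x/L_x, n_y/L_y, n_z/L_z)$ and shell-averages into $|k|$
bins one reciprocal spacing wide. Commensurate vectors make the result
independent of coordinate wrapping. For dense polysaccharide chains the
two characteristic peaks are the intrachain backbone repeat near
$k = 10.5$ nm⁻¹ ($2\pi/k = 0.60$ nm) and the interchain stacking peak
near $14.5$ nm⁻¹ ($0.43$ nm). `structure_factor_at()` evaluates exact
Bragg conditions at explicit vectors; `max_per_shell` caps the per-shell
enumeration (deterministically, evenly spaced in lexicographic order) for
quick looks at large boxes — peak positions from capped runs are
approximate, so quantitative work should enumerate fully. The scatterer
selector defaults to all sites; for atomistic cellulose the conventional
choice is the two β(1→4) linker oxygens per repeat unit, exposed as the
`sites` predicate. No amorphous-background subtraction is attempted:
extracting a crystalline fraction from $S(k)$ requires it, which is
exactly why crystallinity is instead detected in real space (below).

## Crystallinity: the P2 protocol

Chains are cut into consecutive 6-monomer segments — one persistence
length, $l_p = 3.4$ nm at the 0.60 nm repeat (`partition_segments()`);
the segment direction is the block's end-to-end unit vector, the simplest
definition consistent with the partition. `detect_crystallites()` then:

1. marks consecutive intra-chain segment pairs aligned when
   $P_2 = (3\cos^2\theta - 1)/2 \ge 0.95$ (i.e. within 10°),
2. extends maximal runs of aligned segments along the chain,
3. searches for chains whose minimum monomer–monomer distance (minimum
   image) from the crystalline front is below 0.5 nm,
4. admits their segments when $P_2$ against the run's mean direction
   passes the same threshold, and repeats the search from the admitted
   segments until no chain joins (crystallites grow by accretion — a
   single one-shot neighbour search could never assemble a 2×2 bundle at
   0.43 nm spacing, whose diagonal exceeds 0.5 nm),
5. records assemblies of ≥ 4 chains and excludes their chains from
   further iteration; iteration order is ascending chain id, so the
   result is deterministic.

The degree of crystallinity is $d = n_{\mathrm{crystal}}/(N_l N_c)$.
Trailing monomers that do not fill a whole segment are never counted,
biasing $d$ down by at most $2/N_l$ — at $N_l = 50$ a fully crystalline
sample reports $d = 0.96$. $d$ is exactly invariant under rigid rotation
and translation (verified in the tests), and no monomer is ever counted
twice.

## Chain geometry

`persistence_length()` fits
$\langle\cos\theta(s)\rangle = e^{-s/l_p}$ over backbone contour
separations, pooling all chains. The log-linear fit runs through the
origin, is restricted to separations below three first-pass persistence
lengths and correlations above 0.05, and is weighted by
$\langle\cos\theta\rangle^2$ — the delta-method variance of a logarithm
grows as the inverse square of its argument, so unweighted fits let the
noisy tail dominate. Non-decaying correlations (straight chains) are
flagged with a lower bound instead of a number. `end_to_end()` reports
mean end-to-end distances on unwrapped coordinates; wrapped input is
repaired by minimum-image chain walking, valid while every bond is
shorter than half the box. The Kratky–Porod closed form
$\langle R^2\rangle = 2 l_p L - 2 l_p^2 (1 - e^{-L/l_p})$ is exported
(`kratky_porod_r2()`) as the reference the generator/estimator loop must
close.

## The glass transition

`tg_from_specific_volume()` fits two straight lines to $v(T)$ with the
split searched exhaustively over interior grid intervals (at least three
points per segment, for identifiability) and reports the lines'
intersection as $T_g$. A fit statistically indistinguishable from a
single line — F-ratio below the 99 % quantile, exact collinearity, or an
intersection escaping the data range — returns a `no crossover` flag
rather than a number.

## What the synthetic generators emulate — and what they do not

* `gen_mode_trajectory()`: superposed cosines with random phases and
  amplitudes $\propto\sqrt{w_j/m_i}$. This reproduces exactly the two
  properties the spectral pipeline assumes — prescribed spectral weights
  and equipartitioned kinetic energy — and nothing else: no
  anharmonicity, no mode lifetimes.
* `gen_semicrystalline_config()`: straight-chain bundles on a 0.43 nm
  square grid (whole bundles of ≥ 4 chains, so the planted fraction is
  rounded to bundle granularity) inside a melt of worm-like chains whose
  successive bond directions make a fixed polar angle
  $\arccos(e^{-b/l_p})$ with uniform azimuth, giving
  $\langle\cos\theta(s)\rangle = e^{-sb/l_p}$ exactly in expectation —
  the same law the estimator fits, closing the loop. There is no
  excluded volume, no hydrogen bonding, no real glucose chemistry;
  passing tests demonstrate the statistical machinery, not force-field
  realism.
* `gen_ate_series()`: slow exponential plus a fast transient plus
  Gaussian white noise. White noise is an assumption of convenience;
  real microcanonical fluctuations are correlated in time.
* `gen_stress_response()`: linear elastic responses with independent
  Gaussian noise per sample. The two shear records are constructed so
  that both printed $C_{44}$ estimators recover the planted value; the
  default noise in `gen_kappa_bundle()` (0.005 GPa) represents the small
  residual after the noise-cancellation differencing that finite-strain
  protocols rely on, while recovery tests also exercise 0.5 GPa raw
  noise, where only the pooled mean over many seeds is informative.
* `gen_bilinear_v()`: an exactly bilinear curve plus noise — no
  cooling-rate dependence, no curvature near the transition.

All generators are bitwise deterministic given their seed;
`gen_kappa_bundle()` fans a single seed out to per-generator streams.

## Problem sizes and defaults

The bundled analyses and the test suite run on deliberately compact
systems — 4–6-atom mode trajectories of 2–10 ps, melts of 100–500 chains
of 48–50 monomers, 1000–1800-point time series — chosen so that every
statistical tolerance in the tests (2 % on spectral weights and decay
constants, ±0.03 on crystallinity, 5 % on chain statistics) is met with
margin at fixed seeds. Production MD systems (~10⁶ atoms) pass through
the same code paths; only `structure_factor()`'s full lattice enumeration
grows steeply with box size, hence its `max_per_shell` escape hatch.

Defaults that encode the analysis conventions: $P_2 \ge 0.95$,
$r < 0.5$ nm, ≥ 4 chains, 6-monomer segments; $\varepsilon = 10^{-3}$,
stress window 50–150 ps; ATE window 0.02–0.20 ns; VDOS output interval
5×10⁻⁴ ps with a 10 ps record; enthalpy grid step 20 K. Every workflow
report echoes its full effective configuration.

## Known limitations

* Orthorhombic boxes only; triclinic input is rejected.
* The minimum-conductivity model ignores frequency-dependent velocities
  and is known to sit above transient-method estimates by tens of
  percent in strongly bonded chain systems.
* The per-mode/per-atom bookkeeping of the quantum correction must be
  kept consistent by the caller when bypassing the workflow.
* The crystallinity detector's accretion step can admit an occasional
  amorphous segment brushing a crystallite at the alignment threshold;
  at the default parameters this leakage is below 2 % of crystalline
  sites in the tests.
* Text formats only (extended XYZ, GRO, CSV); binary MD formats should
  be converted externally.
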