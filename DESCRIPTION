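Package: celluheat
Title: Vibrational Spectra, Heat Capacity, and Thermal Conductivity of Dense Polysaccharide Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-dynamics studies of heat
    flow in dense amorphous and semi-crystalline cellulose-like polymers.
    Computes the vibrational density of states from the mass-weighted
    velocity autocorrelation function, quantum corrections to the classical
    heat capacity via Bose-Einstein mode weighting, thermal conductivity by
    the minimum-thermal-conductivity model and by the approach-to-equilibrium
    decay method, elastic constants and sound velocities from finite-strain
    stress responses, the collective structure factor, P2-based crystallite
    detection and degree of crystallinity, chain-geometry statistics
    (persistence length, end-to-end distance), and the glass transition from
    specific-volume crossovers. Includes seeded synthetic-data generators
    with known ground truth for every input, so the full pipeline is
    testable without an MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
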