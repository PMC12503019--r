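Package: pulsenet
Title: Frequency-Domain Pulse-Wave Propagation in Arterial Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates one-dimensional arterial pulse-wave propagation in the
    frequency domain using a scattering-matrix waveguide formalism. Vessel
    segments are represented as two-port elements built on Womersley's
    oscillatory viscous-flow solution; junctions, three-element Windkessel
    terminations and an active heart source are multiport/one-port nodes.
    Localized nonlinear losses at stenoses, aneurysms and bifurcations are
    modelled with quasi-steady Borda-Carnot resistances and resolved by a
    fixed-point iteration on the steady flow. Includes harmonic signal
    utilities, waveform error metrics, three built-in benchmark arterial
    networks, and an independent nodal-impedance reference solver for
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
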