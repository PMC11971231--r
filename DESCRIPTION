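Package: microlineal
Title: Analytic Microdosimetry of Protons in Sub-Micron Water Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytic calculation of the dose-mean lineal energy (yD) of
    1 MeV-1 GeV protons in liquid-water spheres of 10-1000 nm diameter,
    and of the radiation-protection quality factor Q derived from it via
    the theory of dual radiation action.  The proton-water interaction is
    described by differential ionization cross sections in the dielectric
    formulation of the relativistic plane-wave Born approximation, built
    on a Drude oscillator parameterization of the liquid-water energy-loss
    function.  Direct (crosser) events use parametric energy-loss
    straggling distributions (log-normal, gamma-Erlang, logistic) combined
    with spherical chord-length statistics; indirect (delta-ray) events
    use a pluggable electron lineal-energy lookup table.  Includes a
    seeded Monte Carlo verifier of the direct-event machinery and
    relative-difference / mean-percentage-deviation statistics against
    externally supplied track-structure datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
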