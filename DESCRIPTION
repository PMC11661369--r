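Package: phantomforge
Title: Design and Characterization of 3-D Printed Tissue-Mimicking Optical Phantoms
Version: 0.1.0
Authors@R: person("phantomforge", "developers", role = c("aut", "cre"),
    email = "phantomforge@example.org")
Description: Tools for the digital side of multi-filament 3-D printed optical
    phantom fabrication: calibration of a linear filament-mixing model for
    absorption and reduced scattering coefficients, constrained inverse design
    of gray/white/translucent mixing ratios on the percentage simplex,
    parametric phantom geometry generation (titration rulers, benchmark tiles,
    quality-assurance and tomography slabs) with watertight mesh export,
    multi-material G-code post-processing (purge towers, z-hop, axis-restricted
    travel, per-channel filament accounting), and a spatial frequency domain
    imaging recovery pipeline (three-phase demodulation, reference calibration,
    per-pixel lookup-table inversion) backed by a White Monte Carlo photon
    transport kernel.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
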