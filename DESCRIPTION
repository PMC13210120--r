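Package: dqcryst
Title: Proton-Distance NMR Crystallography Validation from 2Q-1Q Correlation Intensities
Version: 0.1.0
Authors@R:
    person("dqcryst", "maintainers", email = "dqcryst@example.org", role = c("aut", "cre"))
Description: Validates crystal-structure models of molecular solids against
    fast-MAS double-quantum-single-quantum (2Q-1Q) 1H correlation NMR data.
    From a CIF structure model the package expands symmetry to P1, enumerates
    all periodic 1H-1H contacts up to a cutoff, computes squared effective
    dipolar couplings with optional methyl three-site-jump motional scaling,
    converts them to fractional intensities and r^-6-aggregated effective
    distances, and scores the model against experimental fractional
    intensities with an R-squared statistic and per-pair distance deviations.
    A parallel chemical-shift arm converts computed magnetic shieldings to
    shifts with a fitted reference, assigns experimental shifts to sites by
    minimal-deviation matching, and reports deviation statistics. A synthetic
    data module generates toy crystal structures, noisy fractional-intensity
    sets and synthetic shieldings so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
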