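Package: fibersas
Title: Core-Shell Nanofiber Small-Angle Scattering Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and fits small-angle X-ray and neutron scattering (SAXS/SANS)
    from self-assembled beta-sheet peptide nanofibers. Implements a rectangular
    core-shell(-shell) cross-section form factor for long fibers in the decoupling
    approximation, including a solvent-swollen PEG corona with Beaucage blob
    scattering; computes X-ray and neutron scattering length densities from
    chemical composition including H/D exchange and solves zero-average-contrast
    (ZAC) solvent conditions; performs simultaneous weighted least-squares
    refinement of one structural model against multiple datasets (SAXS + SANS,
    H2O/D2O contrast series) with shared parameters; simulates noisy synthetic
    curves, contrast series and time-resolved ZAC exchange-kinetics decays; and
    provides empirical binding-energy estimators (Tanford group increments,
    backbone hydrogen-bond counts) and circular-dichroism unit conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
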