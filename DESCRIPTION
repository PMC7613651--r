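Package: fluorfold
Title: Co-Translational Folding Thermodynamics from 1D 19F NMR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of one-dimensional 19F NMR data from
    ribosome-nascent chain complexes: exponential apodization, Fourier
    processing and baseline correction of free-induction decays;
    deconvolution of spectra into up to six Lorentzian components with
    time-domain model-count selection (BIC) and bootstrap-of-residuals
    uncertainties; conversion of state populations into co-translational
    free-energy landscapes with detection-limit bounds; Bloch-McConnell
    simulation and fitting of chemical exchange saturation transfer (CEST)
    profiles and on-resonance R1rho rates for slow-exchange kinetics; and
    Stejskal-Tanner stimulated-echo diffusion fits for sample-integrity
    checks. Includes a synthetic-data generator emulating four-state
    nascent-chain 19F spectra so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
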