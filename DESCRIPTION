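Package: smtpm
Title: Single-Molecule Tethered Particle Motion Analysis of Helicase DNA
    Unwinding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-molecule tethered particle motion (smTPM)
    recordings of replicative helicase DNA unwinding. Provides a fork-substrate
    geometry model, a seeded simulator of tethered-bead centroid trajectories
    whose Brownian-motion amplitude is affine in unwound base pairs, windowed
    mean-squared-displacement processing with drift correction and symmetry
    quality control, Brownian-motion-to-base-pair calibration, derivative-band
    detection of unwinding onset with slope and dwell-time velocity estimators,
    and ensemble kinetics: nonparametric bootstrap of mean velocities,
    Michaelis-Menten ATP dependence, NADH-coupled ATPase rates, gel-shift
    unwinding normalization, and tether-disappearance time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
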