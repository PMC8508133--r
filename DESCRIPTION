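Package: smres
Title: Single-Molecule Residence Times from Time-Lapse Imaging
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of chromatin residence times of DNA-binding proteins
    from live-cell single-molecule time-lapse imaging. Provides a kinetic
    simulator of bound and freely diffusing molecules under interleaved
    illumination schedules with single-step photobleaching and Gaussian-PSF
    movie rendering, spot detection by a local signal-to-noise criterion,
    nearest-neighbour track linking with gap closing and confinement-based
    classification of bound molecules, assembly of fluorescence survival-time
    distributions, global inverse-Laplace inference of dissociation-rate
    spectra by non-negative least squares with a shared per-frame
    photobleaching number, and subsampling-based uncertainty estimates for
    the slowest dissociation-rate cluster (the long-lived binding time).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
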