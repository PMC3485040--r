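Package: mriqa
Title: Reproducibility and Quality-Assurance Metrics for Multimodal MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Scanner quality-assurance and test-retest reliability toolkit
    for multimodal brain MRI. Implements structural metrics (global
    intensity normalization, ROI volumetry, affine stretch-factor
    decomposition, background-intensity motion screening), BOLD temporal
    signal-to-noise with a smoothing / high-pass / nuisance-regression
    preprocessing chain, diffusion-tensor estimation with fractional
    anisotropy and mean diffusivity summaries, and the reliability
    statistics (one-way ANOVA, intraclass correlation) used to compare
    scanner conditions. Ships synthetic structural, BOLD and diffusion
    phantoms with known ground truth so every metric is testable without
    scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), methods
Imports:
    stats,
    utils,
    RNifti,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    oro.nifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
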