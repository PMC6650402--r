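Package: bioradr
Title: Quantification of Dynamic [18F]FDG Bioradiography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying dynamic autoradiography (bioradiography)
    of living tissue incubated with the PET tracer [18F]FDG. Converts
    storage-phosphor plate readouts from photostimulated luminescence (PSL)
    to 80 kV X-ray-equivalent dose rates, decay-corrects multi-frame
    exposure series to a common reference time, estimates per-tissue
    irreversible uptake rates by linear regression, compares treatment
    groups against a shared control with a permutation Steel rank test,
    and computes simplified MIRD decay and dosimetry arithmetic. Includes
    a synthetic multiwell phantom simulator (tracer trapping kinetics,
    competitive glucose inhibition, physical decay, Poisson noise, and the
    plate's saturating logarithmic response) that provides ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    graphics,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
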