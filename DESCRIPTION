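Package: hstax
Title: Hybrid Subtomogram Averaging to Single-Particle Export Toolkit
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational core of the hybrid subtomogram-averaging (hStA)
    workflow for cryo-electron tomography. Builds dose-redistributed
    (dose-symmetric) tilt schemes with per-image exposure bookkeeping,
    normalizes micrograph statistics according to a dose-based variance
    relation, and exports refined 3D subtomogram poses into 2D
    single-particle metadata (micrograph coordinates, ZYZ Euler angles and
    per-particle defocus from tomogram Z-height) for the high-dose zero-tilt
    image. Includes readers and writers for IMOD tilt-series alignment files
    (.tlt/.xf), Dynamo-style particle tables, STAR particle metadata and
    MRC2014 images; a CTF model with restricted-frequency defocus-estimation
    precision analysis and phase-flip versus Wiener 2D correction; a
    misalignment-injection experiment; and a synthetic phantom scenario
    generator with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
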