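Package: circumscan
Title: Circumferential Surface Microscopy of Excised Organs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational core for automated circumferential surface
    microscopy of excised organs imaged against a glass slide over
    repeated rotations. Provides closed-form and numerical
    coverage-geometry models for a compressible sphere, acquisition
    planning, structured-illumination square-law optical sectioning,
    flat-field correction, serpentine tile mosaicking into rolled-out
    circumference panoramas, ink-fiducial panel registration with
    slippage detection, Otsu-based tissue-coverage quantification
    against triangulated surface meshes, and a synthetic phantom
    generator so every stage is testable without real specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite,
    optparse
Config/testthat/edition: 3
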