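Package: radrepro
Title: Reproducibility Analysis of PET Radiomic Features
Version: 0.1.0
Authors@R: person("radrepro", "developers", role = c("aut", "cre"),
    email = "radrepro@example.org")
Description: Extracts 79 radiomic features (gray-level co-occurrence,
    run-length, size-zone and neighborhood gray-tone difference texture
    families plus shape and intensity-volume-histogram features) from masked
    3D PET volumes in SUV units, and quantifies feature reproducibility
    across segmentation-mask variants, fixed-bin-count gray-level
    discretizations and reconstruction-style image variants using mean
    percentage differences, Bland-Altman reproducibility limits,
    reproducibility classification bands, and intraclass correlation
    coefficients with confidence-interval precision. Includes a synthetic
    phantom generator that emulates heterogeneous tumor uptake, correlated
    observer segmentations and reconstruction-dependent smoothing/noise, a
    minimal NIfTI-1/NRRD volume codec, and a study pipeline that produces a
    per-feature reproducibility report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
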