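Package: mwstroke
Title: Microwave Head-Imaging Simulation, TSVD Born Reconstruction and
    Stroke-Type Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a 10-port, 1 GHz microwave head-imaging system on a
    liquid head phantom with spherical stroke inclusions. Provides a
    first-order Born forward model with analytic point-source fields in the
    lossy background, truncated-SVD (TSVD) regularized reconstruction of
    dielectric-contrast changes, generation of labeled S-matrix datasets
    emulating fixed-position and random-position measurement campaigns, and
    a PCA plus Gaussian-kernel SVM classifier for ischemic versus
    hemorrhagic versus no-stroke decisions, evaluated with confusion
    matrices and Cohen's kappa. Includes Touchstone import/export and a
    seeded end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
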