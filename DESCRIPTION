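Package: avoripen
Title: Ripening Assessment and Shelf-Life Estimation for 'Hass' Avocados
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Image-based ripening-stage classification and shelf-life
    management for 'Hass' avocado (Persea americana) storage studies.
    Simulates labelled ripening-image cohorts across storage regimes
    (10 C, 20 C, fluctuating room temperature), builds leakage-free
    sample-grouped train/validation/test splits with random oversampling,
    extracts calibrated CIELAB colour palettes by k-means, trains a compact
    ripening-stage classifier with a step learning-rate schedule and
    early stopping, scores predictions with margin-of-error and per-sample
    best-side accuracy, and converts stage classifications into shelf-life
    estimates with forced-endpoint through-origin regression, loss analysis
    and kernel density estimation of the losses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    withr,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
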