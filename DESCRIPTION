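Package: rtica
Title: Real-Time ICA Monitoring of fMRI Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates real-time monitoring of a target independent component
    in functional MRI. An ICA functional localizer identifies the network of
    interest, after which four volume-by-volume monitoring engines estimate
    its activation: static back-projection onto the localizer map, and three
    recursive sliding-window variants that exploit temporal, spatial, or
    spatio-temporal priors. Includes a symmetric fixed-point FastICA
    implementation with constrained single-component extraction, a synthetic
    BOLD generator with retained ground truth for validation, and evaluation
    utilities for spatial/temporal correlation and run-to-run stability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
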