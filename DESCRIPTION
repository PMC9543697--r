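Package: filmratio
Title: Radiochromic Film Calibration from Dose Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates net-optical-density to dose calibration functions for
    radiochromic film (e.g. Gafchromic EBT3) from repeated scans of the same
    relative dose profile delivered at different monitor-unit scalings. The
    ratio of reconstructed doses at any two scalings must be constant across
    the profile; the calibration parameters are found by minimising a cost
    that enforces this, anchored by one or more absolute reference doses.
    Includes the scanner-image front end (net optical density, centre
    finding, radial rebinning), bimolecular and polynomial calibration
    families with analytic gradients, multi-restart gradient-based fitting,
    a synthetic measurement generator, and train/test evaluation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
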