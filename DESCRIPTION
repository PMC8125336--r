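Package: swayrisk
Title: Wearable-Sensor Screening of ACL Injury Risk from Jump-Landing Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess anterior cruciate ligament (ACL) injury risk in
    athletes from a single shank-mounted inertial measurement unit and
    optoelectronic bars. Implements static re-alignment and Mahony
    complementary-filter orientation estimation, posturographic sway metrics
    (Prieto path lengths and the 99% confidence-ellipse area) on the projected
    vertical axis, jump-landing event detection (ground contact, stabilization
    time) and single-leg-squat descent analysis, Landing Error Scoring System
    (LESS) aggregation and risk labelling, a nine-classifier cross-validated
    benchmark with accuracy, F1 and the ROC-space goodness index, and
    random-forest out-of-bag permutation importance. A two-tier synthetic-data
    generator produces feature-level cohorts calibrated to published group
    statistics and signal-level trials with known ground-truth features, so the
    whole pipeline is testable without access to athlete data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    class,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
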