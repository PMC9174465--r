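Package: mocapuq
Title: Uncertainty Propagation for Marker-Based Motion Capture Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies the uncertainty in joint angles, net joint moments,
    and joint powers computed from marker-based motion capture that is due to
    errors in marker registration (where markers sit on each model segment)
    and in body-segment scaling. Builds Monte Carlo ensembles of equally
    plausible link-segment models (marker positions perturbed uniformly in a
    ball of radius e; segment scale factors drawn from an interval and
    accepted by a posed marker-distance check), runs every ensemble member
    through the same constrained inverse-kinematics, low-pass filtering,
    inverse-dynamics, and joint-power pipeline, and reports per-level marker
    error metrics, ranges of nine peak gait metrics, and the consequences for
    crouch-gait classification. Includes readers and writers for TRC and
    MOT/STO motion-capture files and a synthetic-gait generator that produces
    dynamically consistent fixtures for offline testing.
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
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
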