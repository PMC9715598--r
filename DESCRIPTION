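Package: kamdecomp
Title: Decomposition of the Knee Adduction Moment from the Ground Reaction Vector
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes the external knee adduction moment (KAM) during the
    stance phase of gait from the ground reaction vector (GRV) and splits it
    into four biomechanically interpretable components: mediolateral ground
    reaction force acting over knee height (M1), vertical force over the
    frontal-plane knee-ankle offset (M2), vertical force over the medial
    offset of the centre of pressure from the foot axis (M3), and vertical
    force over the anterior centre-of-pressure position combined with the
    foot progression angle (M4). Includes a two-segment Newton-Euler inverse
    dynamics reference, KAM feature extraction (peaks and angular impulse),
    inter-protocol coefficient of multiple correlation and Bland-Altman
    agreement statistics, and a parametric stance-phase gait simulator with
    analytically known component ground truth.
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
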