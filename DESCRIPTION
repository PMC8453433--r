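Package: nawmtrack
Title: Backward Analysis of Normal-Appearing White Matter Before New MS Lesion Formation
Version: 0.1.0
Authors@R: person("NAWM", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal MRI analysis of normal-appearing white
    matter (NAWM) in multiple sclerosis before new T2 lesion formation:
    scanner calibration and normalization of MTR, T1-weighted and T2-weighted
    intensities (including least-trimmed-squares longitudinal fits), new-T2
    lesion detection and tracking, pre-lesion / contralateral / overall-NAWM
    region-of-interest geometry with mirror matching, patient-weighted nested
    linear mixed-effects modelling with AR(1) residual correlation and
    least-squares means, voxel-wise NAWM-abnormality and lesion-probability
    atlas construction with binned trend tests, and a synthetic longitudinal
    cohort generator with known injected pre-lesion abnormalities that
    exercises the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
RoxygenNote: 7.3.3
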