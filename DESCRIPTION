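Package: bioapatite
Title: Physicochemical Analysis of Bone Bioapatite Across the Postmortem
    Interval, Before and After Burning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying early diagenetic change in bone bioapatite
    and its survival through burning. Provides a calibrated synthetic-data
    generator for ATR FT-IR spectra and zonal electron-microprobe (EMPA)
    oxide tables; baseline correction, peak-height extraction and the
    standard battery of infrared indices (IRSF, C/P, BPI, API, C/C, CN/P,
    CO/CO3, N/P, APR, PHT) with categorical heat markers (beta-TCP,
    cyanamide, OH-Cl); detection-limit censoring, quality-control
    filtering, oxide-to-element conversion and Ca/P molar ratios for EMPA
    point data; a chemometric suite (scaling, regression against
    postmortem interval, PCA, linear discriminant analysis, MANOVA with
    pairwise Hotelling post hoc tests); and interpretive decision rules
    for burnt/unburnt discrimination, maximum-temperature banding and
    potassium-threshold inference of the postmortem interval preceding
    cremation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
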