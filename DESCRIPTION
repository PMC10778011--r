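Package: breslowmsi
Title: Preoperative Breslow Thickness Staging from Multispectral Imaging
    and High-Frequency Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the Breslow thickness category of primary
    cutaneous melanoma from non-invasive imaging. Implements ImageJ-style
    intensity and shape descriptors (mean gray value, circularity, solidity,
    roundness) for multispectral lesion images, a three-threshold decision
    tree that stages lesions into the clinical <1 mm, 1-2 mm and >2 mm
    groups, a simulated optically guided high-frequency ultrasound
    measurement, multivariate regression of thickness on spectral features,
    and a complete diagnostic-accuracy engine (multi-class confusion
    matrices, one-vs-rest and micro-averaged sensitivity/specificity/PPV/NPV,
    Cohen's kappa with asymptotic confidence intervals, per-category mean
    squared error, and reconstruction of published accuracy tables from
    their per-class rows). A reproducible synthetic-cohort generator with
    rendered lesion images stands in for clinical data.
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
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
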