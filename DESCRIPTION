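Package: lvecho
Title: Left-Ventricle Volume Curves and Automatic End-Diastole/End-Systole
    Detection from 2D Echocardiography by Level-Set Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments the left-ventricular endocardial border in every frame
    of a 2D echocardiographic image sequence with an edge-stopped level-set
    active contour, converts each contour to a volume by single-plane disk
    summation, builds the volume-time curve, detects end-diastole and
    end-systole frames from its per-cycle extrema, and reports stroke volume,
    ejection fraction and cardiac output together with agreement statistics
    (error metrics, linear regression, Bland-Altman limits of agreement,
    paired t-test). Ships a synthetic beating-ventricle speckle phantom with
    analytic ground truth so the whole pipeline is testable without patient
    data, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    yaml
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
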