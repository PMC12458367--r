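Package: vescap
Title: Quantification of Golgi Vesicle Capture at the Yeast Bud Neck
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the capture of Golgi-derived transport
    vesicles at the yeast bud neck and for kinetic mapping of cisternal
    maturation. Implements the mask-overlap capture statistic (per-slice
    channel thresholding, Golgi-mask subtraction, a 65 percent mask-removal
    quality-control rule, and the fraction of cargo signal inside the
    subtraction-modified septin mask), processing of per-cisterna
    fluorescence traces (photobleaching correction, smoothing,
    normalization, landmark alignment, averaging, residence-time
    estimation, and partial-overlap windows), the cryo-electron-tomography
    capture-zone geometry with sphere-intersection vesicle scoring, Welch's
    t comparisons with significance labeling and categorical tabulation,
    and synthetic-data generators (confocal stacks, maturation traces, and
    tomogram vesicle models) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
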