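Package: stentorshape
Title: Cell-Shape Morphometrics for Elongated Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the proportionality of elongated single-cell
    silhouettes such as those of the giant ciliate Stentor coeruleus.
    From a brightfield-style image the pipeline binarizes and smooths the
    cell, extracts the outline and a skeleton-based midline, measures
    perpendicular chord widths every 10 pixels along the midline, and
    summarises each cell by a unit-less shape factor: the ratio of the
    trapezoidal-rule integrated width area between the tail and the oral
    apparatus (the widest point) to the area of the right trapezoid
    spanned by a straight line between them. Straight-sided (conical or
    cylindrical) cells score 1; wine-glass tapered cells score below 1.
    Includes a parametric synthetic-silhouette generator with exact
    analytic ground truth, cohort-level trend curves and Welch group
    comparison, and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    pracma,
    stats,
    grDevices,
    utils,
    tibble,
    jsonlite,
    png,
    tiff,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
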