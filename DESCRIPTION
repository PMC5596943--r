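Package: stratkit
Title: Evaluation and Refinement of Cluster Stratifications
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for clustering record-by-feature matrices (patients by
    genes and similar omics layouts), quantifying how well every record fits
    its own and every other cluster under interchangeable distance and
    correlation metrics, thresholding fuzzy c-means memberships, and refining
    stratifications with split, shift, merge and exclude operators. Includes
    stratification overlap comparison, per-group Kaplan-Meier and categorical
    context summaries, seeded synthetic-data generators with known ground
    truth, and a command-line interface with a static HTML/SVG report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
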