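Package: driftlab
Title: Ground-Truth Benchmarking of Drift Correction for Reading
    Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating vertical drift correction in reading
    eye-tracking experiments against known ground truth. Generates
    realistic synthetic multi-line reading trials (optimal-viewing-position
    landing sites, word-length-scaled durations, word skipping, within- and
    between-line regressions), injects parametric drift distortions
    (Gaussian vertical noise, x-dependent slope, line-dependent shift,
    constant offset), corrects them with nine automated line-assignment
    algorithms (attach, chain, cluster, merge, regress, segment, split,
    stretch, warp), and scores the results with line-assignment accuracy,
    multi-rater per-fixation agreement, and the intra-class correlation
    coefficient ICC(3,1). A benchmark driver orchestrates the full
    generate-distort-correct-evaluate pipeline reproducibly under a single
    seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
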