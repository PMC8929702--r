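Package: contness
Title: Conditional Gene Essentiality from Transposon Insertion Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Model-based identification of conditionally beneficial and
    conditionally detrimental genes from transposon insertion sequencing
    (Tn-seq and RB-TnSeq) count data. Site-level insertion counts are
    aggregated to per-gene total and unique count matrices, each gene is fit
    with a ridge-penalized negative binomial regression over a nested
    genetic-background/environment design, and genes are called by an
    empirical-null local false discovery rate applied to both count flavors,
    retaining only calls supported by total and unique counts. Includes
    count-data simulators and an evaluation harness for benchmarking the
    regularized fit against unregularized and zero-inflated negative
    binomial baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    splines,
    jsonlite
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
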