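Package: aidnipt
Title: Fragment-Distance Based Non-Invasive Prenatal Aneuploidy Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects fetal trisomy 21, 18 and 13 from low-coverage cell-free DNA
    (cfDNA) sequencing using fragment distances (FD) instead of fragment counts.
    Aligned fragments are positionally shifted, adjacent-fragment distances are
    summarized per 1-Mb bin (mean, median, IQR), normalized values for a target
    chromosome and three internal control chromosomes are rasterized into
    target-repeat-stacking (TRS) grayscale images, and small per-trisomy
    convolutional networks plus a median ensemble classify each sample.
    Conventional count-based Z-score and normalized chromosomal value (NCV)
    callers are included as baselines, together with a cfDNA fragment simulator
    with known trisomy status, fetal fraction, GC bias and maternal CNV
    spike-ins, and confusion-matrix metrics with normal-approximation
    confidence intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    Rsamtools,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
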