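Package: rankDE
Title: Exact Rank-Sum Differential Expression Selection for Small-Sample
    Microarray Pivot Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Re-implements a summary-level microarray analysis pipeline for
    very small group sizes (3 vs 3 and 4 vs 4 arrays): per-array trimmed-mean
    global scaling to a target intensity, a signal floor before log2
    transformation, permutation-exact two-tailed Mann-Whitney rank-sum tests
    with enumeration of all group assignments, and a four-criterion
    differential-expression filter combining fold change, detection calls,
    the exact p-value with an adaptive minimum-achievable-p rule, and a
    pairwise cross-group consistency requirement. Downstream tools build
    three-way direction cross-tabulations across contrasts, test gene-list
    overlaps against contingency-table independence, tally genes by
    annotation keywords, and compute dual-luciferase reporter fold
    activation. A synthetic-data generator emulates the two-genotype,
    two-age study design with known ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
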