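Package: sere
Title: Replicate Quality Control for RNA-Seq Count Data via the Simple
    Error Ratio Estimate
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quality control and global comparison of RNA-Seq count
    datasets with the Simple Error Ratio Estimate (SERE), a
    single-parameter over/under-dispersion statistic for deciding whether
    lanes are faithful replicates (SERE = 1), duplicates (SERE = 0), or
    globally different (SERE > 1). Includes chi-square based confidence
    intervals, pairwise SERE matrices and SERE-based hierarchical
    clustering with Newick export, the two classical comparator
    statistics (Pearson correlation on log-RPKM with a pseudo-count, and
    Cohen's simple and weighted Kappa over RPKM bins), and an in-silico
    simulation framework that draws replicate, depth-sweep, unequal-split
    and contamination experiments from finite read pools by exact
    multivariate hypergeometric sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
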