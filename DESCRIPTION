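Package: plstarget
Title: miRNA Target Prediction from Paired Expression Profiles by Partial Least Squares
Version: 0.1.0
Authors@R: person("plstarget", "developers", role = c("aut", "cre"),
    email = "plstarget@example.org")
Description: Infers microRNA (miRNA) targets from jointly measured miRNA and
    mRNA expression profiles of the same samples. Differentially expressed
    genes are screened by unpaired t-tests with Benjamini-Hochberg false
    discovery rate control and fold-change filters; up-regulated mRNAs are
    then regressed on down-regulated miRNAs by multi-response partial least
    squares (PLS), and each original-scale association score is tested for
    significant negative (inverse) association by a leave-one-miRNA-out
    residual bootstrap. Significant pairs form a bipartite miRNA:mRNA network
    exportable to Cytoscape formats. A derangement-permutation simulation
    estimates the chance false detection rate of any pair-calling rule and
    calibrates a pairwise-correlation baseline to a matched rate. A synthetic
    paired-data generator with planted inverse regulatory edges supports
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
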