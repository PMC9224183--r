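Package: gwgendrug
Title: Network Identification, Principal Network Projection and
    Drug-Combination Design for Systems Drug Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies data-supported genome-wide genetic and epigenetic
    networks (GWGENs) from candidate interaction tables and expression data
    by per-node constrained least squares with AIC model-order detection,
    extracts core networks by principal network projection (SVD energy
    ranking of the combined ability matrix), trains a feed-forward neural
    network classifier for drug-target interaction prediction, and assembles
    multi-molecule drug combinations under expression-reversal and toxicity
    filters.  Ships a synthetic-data module that plants ground-truth networks
    and generates expression, drug-target and drug-annotation data so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pracma,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
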