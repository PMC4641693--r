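Package: mirlocate
Title: Locating Mature miRNAs Within Plant Pre-miRNA Hairpins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Locates the mature miRNA within a pre-miRNA hairpin. Candidate
    guide strands are enumerated along the precursor, each candidate's
    miRNA:miRNA* duplex is derived from the folded secondary structure and
    encoded as a fixed 440-dimensional vector of sequence, structural and
    positional-entropy features, candidates are scored by an imbalance-aware
    classifier (random forest by default), and the mature miRNA is placed by
    an argmax over per-position summed scores. Includes a pluggable folding
    engine (ViennaRNA RNAfold wrapper plus a maximum-pairing fallback), a
    constrained negative sampler with configurable positive:negative ratio,
    grouped stratified cross-validation with ROC/AUC reporting, Gini feature
    ranking, a synthetic hairpin simulator with planted guides, and
    resolution-d evaluation of predicted start/end positions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    e1071,
    rpart,
    class,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
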