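Package: mirassoc
Title: Integrative microRNA-mRNA Association Mining with Mutual Information
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Screens paired microRNA and mRNA abundance panels for putative
    repressive regulatory relationships. Expression matrices are filtered by
    abundance and dynamic range, every miR x mRNA pair is scored with
    Pearson's correlation and a Kraskov-Stoegbauer-Grassberger (algorithm 2)
    k-nearest-neighbour mutual-information estimate, and strong negative
    associations are intersected with percentile-filtered sequence-based
    target predictions and experimentally validated interactions. Per-miR
    enrichment of active associations, Gene Ontology substring enrichment of
    target lists, and a phenotype-separation score quantifying how well each
    pair separates high- and low-invasiveness sample groups complete the
    workflow. A seeded synthetic-data generator produces all pipeline inputs
    with planted regulatory structure for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    limma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
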