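Package: herbdissect
Title: Dissecting Early Transcriptomic Responses to Herbivory via Cumulative Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect early plant transcriptomic responses to insect
    herbivory into the contributions of individual herbivory-associated cues.
    Implements sequential trichotomous differential-expression contrasts that
    classify genes into 27 expression patterns and extract robust gene modules,
    an internal negative-binomial Wald test with median-of-ratios size factors
    and trended moment dispersions, transcriptome inducibility via the relative
    distance plasticity index (RDPI), hypergeometric GO enrichment with
    Jaccard-similarity functional networks, clustering-coefficient connectivity
    statistics, topological-overlap clustering of gene modules, and
    treatment-to-treatment inductive similarity (signed DEG-vector cosine
    similarity and global fold-change regression). Ships a negative-binomial
    count simulator that plants known response patterns so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
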