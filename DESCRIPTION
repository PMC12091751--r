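Package: stressready
Title: Cross-Species Drought Transcriptomics and Stress-Ready Expression Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative transcriptomics pipeline for two-species stress
    experiments. Builds one-to-one ortholog maps from reciprocal alignment
    hits (best bidirectional hits), applies transcript-length normalization
    to expression estimates, runs negative-binomial differential-expression
    contrasts within and between species, and classifies every ortholog pair
    into one of fifteen expression-model cases centred on "stress-ready"
    genes (constitutive pre-adaptation, where one species' control-level
    expression matches the other species' stressed level). Downstream stages
    provide hypergeometric term enrichment with purified-term filtering and
    random-gene negative controls, position-weight-matrix promoter scanning
    with exact p-values and Fisher motif enrichment, tree-ensemble gene
    regulatory network inference with top-fraction and motif-presence edge
    filtering, and directed-edge Jaccard comparison of the resulting
    networks. A ground-truth synthetic-data generator emulates every input
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
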