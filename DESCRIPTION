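Package: cnamil
Title: Attention-Based Multiple-Instance Learning for Copy-Number Aberration Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A three-stage pipeline for pan-cancer analysis of gene-level
    somatic copy-number aberration (CNA) profiles: recursive feature
    elimination with cross-validation over gene features, a multi-class
    attention-based multiple-instance learning classifier with gated
    attention pooling, and attention-derived per-cancer-type CNA signature
    generation. Includes signature-comparison metrics (gain/loss frequency
    profiles, chromosome-arm Spearman concordance, gene-set Jaccard
    overlap) and a synthetic cohort simulator of five-level discrete
    copy-number calls with planted class-specific aberration blocks, so the
    whole method can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
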