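Package: notegate
Title: Rubric-Based Clinical Feature Extraction Scoring with Confidence
    Regularization and a Matching Gate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-agnostic machinery for scoring free-text patient notes
    against case-specific feature rubrics. Provides character n-gram F1
    (chrF-style) bidirectional matching between extracted and gold features
    with hallucination and omission penalties, a confidence-regularization
    objective with dynamic thresholds and epoch feedback, a three-step
    inference matching gate (exact/Levenshtein, sentence TF-IDF, windowed
    overlap) that emits character-offset evidence spans, and a full
    evaluation harness: binary-overlap and semantic presence scoring,
    precision/recall/F1, calibration (ECE, Brier, reliability tables),
    error accounting with percent reductions, paired bootstrap and McNemar
    comparisons, and a review queue for borderline matches. A seeded
    synthetic-corpus generator and mock extractor make the whole pipeline
    testable end to end without any clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
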