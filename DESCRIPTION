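Package: coxfuse
Title: Multimodal Survival Prediction with Attention-Based Modality Fusion
    and a Neural Cox Hazard
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Fits deep Cox proportional-hazards models on multimodal patient
    data: a clinical table (cancer type, gender, race, histological type, age)
    plus mRNA, miRNA and gene copy-number matrices. Modality-specific encoders
    map each data type to a fixed-length representation; a margin-based
    cross-modal similarity loss with random in-batch pairing aligns
    representations across modalities; per-feature attention weights fuse them
    into a single patient vector feeding a non-linear Cox hazard head trained
    by the average negative partial log-likelihood. Includes preprocessing
    (variance filtering, min-max scaling, split and cross-validation helpers),
    a censored concordance index, PCA projection of learned representations,
    and a synthetic multi-omics survival-data generator so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
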