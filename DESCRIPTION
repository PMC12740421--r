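Package: lungfuse
Title: Multimodal Dynamic Fusion for COPD Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements a multimodal dynamic fusion pipeline for chronic
    obstructive pulmonary disease (COPD) risk stratification from chest-image,
    lung-function and environmental-exposure data. A dual-tower architecture
    aligns image and tabular-clinical embeddings in a shared space with a
    temperature-scaled symmetric contrastive (InfoNCE) objective; a conditional
    Wasserstein GAN with gradient penalty imputes missing environmental
    exposure variables conditioned on clinical attributes; and a
    patient-attribute-driven softmax gating network fuses the three modality
    embeddings as a convex combination before classification. Ships a
    synthetic case-control cohort generator with procedurally rendered
    lung-like images so the full pipeline trains and validates at desk scale,
    plus evaluation metrics, an ablation runner and subgroup weight reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
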