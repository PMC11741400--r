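Package: kinfuse
Title: Explainable Multimodal Prediction of Human Traits from Head
    Motion, Facial Action Units and Speech
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns interpretable head-motion primitives ("kinemes") from
    Euler-angle time series via non-negative matrix factorization and
    Gaussian mixture clustering, encodes facial action units and speech
    low-level descriptors on a shared two-second window grid, and trains
    recurrent neural models (unimodal, feature-fusion, additive
    soft-attention fusion and decision fusion) to predict continuous and
    median-dichotomized human-centered traits from thin behavioral
    slices. Provides two explanation surfaces: percentile-dominant
    behavioral patterns and per-modality attention contributions. Ships a
    synthetic multimodal corpus generator with known ground truth so the
    full pipeline is testable without restricted corpora.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
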