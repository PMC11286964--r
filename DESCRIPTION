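Package: coxformer
Title: Joint Longitudinal Forecasting and Survival Prediction with a Causal
    Transformer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Joint modelling of longitudinal clinical biomarkers and
    right-censored time-to-event outcomes in randomized oncology trials. A
    causal (masked) temporal self-attention encoder is pre-trained on
    autoregressive biomarker forecasting and then fine-tuned, with a frozen
    backbone, on Cox partial-likelihood event heads for progression-free
    survival, overall survival and adverse events. The package includes a
    synthetic two-arm randomized-trial simulator with latent disease-burden
    dynamics and proportional-hazards event generation, clinical normal-range
    normalization with an invertible squashing non-linearity, IPCW (Uno)
    truncated concordance evaluation against a last-observation-carried-forward
    baseline, bootstrap-aggregated ensembles, individual treatment-effect
    (CATE) estimation with median-threshold policy learning, surrogate
    decision-tree subgroup discovery, and hidden-state introspection tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
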