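Package: voicelearn
Title: Similarity-Controlled Voice-Learning Experiments and
    Signal-Detection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to design, simulate and analyse short-term voice-learning
    experiments that contrast implicit exposure (a same-different voice
    discrimination task) with explicit listen-and-memorize training.
    Provides similarity-controlled stimulus selection from speaker
    embeddings and mean fundamental frequency (consolidated cosine
    similarities, delta-F0 fusion, ranked Euclidean distances, disjoint
    pair extraction), counterbalanced two-phase experiment plans with
    old-new recognition tests at two voice loads, an equal-variance
    signal-detection simulator of trial-level behaviour with participant
    heterogeneity, and the analysis stack: corrected d-prime estimation,
    soft-ceiling chi-square diagnostics, per-speaker percent correct,
    Welch and Spearman group statistics, linear mixed-effects models and
    a parameter-recovery harness. An audio pre-processing pipeline
    (midpoint snippet extraction, RMS normalization, resampling) is
    included for stimulus preparation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
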