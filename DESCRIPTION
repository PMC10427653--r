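Package: cadsv
Title: Subjective Values of Emotion-Regulation Strategies via Cognitive and
    Affective Discounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Cognitive and Affective Discounting (CAD)
    paradigm for quantifying subjective values (SVs) of emotion-regulation
    strategies (distraction, distancing, expressive suppression) without
    assuming an objective difficulty order.  Provides the adaptive monetary
    titration engine (equal-value round followed by a six-presentation
    halving staircase), the SV computation and per-participant aggregation,
    parametric simulated decision agents for validating SV recovery, a
    synthetic-study generator emulating a 120-participant block design with
    ratings, facial-EMG summaries and questionnaire scores, a facial-EMG
    preprocessing chain (band-pass, notch, rectification, integration,
    baseline correction), and the downstream statistical pipeline:
    random-intercept multilevel models with within-cluster centering and
    ICC, repeated-measures ANOVA with Greenhouse-Geisser correction,
    predicted-versus-actual choice chi-square, ordinal and multinomial
    choice regression, and the flexibility (slope/intercept) regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    MASS,
    nnet,
    signal,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
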