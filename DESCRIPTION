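Package: copatterns
Title: Congruence Analysis of Physical-Activity and Dietary Lifestyle Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering and comparing lifestyle behavior patterns
    from physical-activity (IPAQ long form) and food-frequency (QEB)
    questionnaires. Scores questionnaires into MET-min/week and times/day
    features, imputes missing diet responses, normalizes with the Yeo-Johnson
    transformation, builds Ward dendrograms of items and participants, and
    quantifies congruence between dendrograms with tanglegram entanglement
    minimization, Mantel tests, cophenetic correlation, Baker's Gamma, and
    the Fowlkes-Mallows index. Includes k-means subgrouping with elbow and
    silhouette model selection, body-composition association testing (ANOVA
    with Tukey HSD, distribution-free median confidence intervals), a
    self-report agreement regression, and a synthetic-cohort generator with
    planted cluster and congruence structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
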