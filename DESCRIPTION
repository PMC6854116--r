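Package: coniferisk
Title: Risk Models for High-Impact Invasions by Non-Native Conifer-Specialist Insects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Logistic submodels and a composite risk equation for predicting which
    non-native conifer-specialist insects will cause high-impact invasions (host
    mortality at the population or regional scale) on novel North American conifer
    hosts. Implements AICc multimodel inference with Akaike weights and confidence
    sets, guild-stratified quadratic divergence-time models on a dated host
    phylogeny, a native-congener presence model, host-trait models, Blomberg's K
    phylogenetic-signal randomization test, availability-aware composite risk
    pooling in logit space, binned calibration, Nagelkerke R-squared, 10-fold
    cross-validation and ROC/AUC evaluation, plus a synthetic census generator
    for end-to-end simulation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
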