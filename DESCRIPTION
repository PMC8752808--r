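Package: attnmod
Title: Attentional Modulation Analysis of Decoded Visual Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear decoding of hierarchical image features from visual-cortex-like
    response patterns, with three analyses of attentional modulation: weighted-contrast
    peak modeling of decoded feature patterns against superimposed-stimulus features,
    pair-wise image identification by feature correlation, and amplitude modulation of
    image-specific feature sets. Includes a deterministic hierarchical feature bank, a
    toy stimulus generator, an encoding-model simulator that injects a known attentional
    weight so every stage can be validated by parameter recovery, the statistical layer
    (effect sizes, one-sided t tests, Bonferroni correction, permutation tests, post-hoc
    power, normality checks), and a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
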