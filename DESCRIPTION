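Package: orthoprime
Title: Letter-Order Coding Models and Masked Orthographic Priming
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for computational modelling of letter-position coding in
    visual word recognition. Implements open-bigram extraction under
    configurable policies (gap limits, edge markers, distance weights,
    Gaussian positional noise), prime-target match scores for the competing
    coding schemes (binary open bigram, distance-weighted open bigram,
    noisy-position open bigram, slot coding, and a simplified spatial
    activation gradient), construction of masked-priming stimuli
    (transposed-letter, substituted-letter, bigram, and all-letter-different
    primes), condition-level priming-effect arithmetic with a
    zero-overlap falsification check of model predictions, and a
    trial-level synthetic data generator for cross-case same-different
    reaction-time experiments with crossed subject and item effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
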