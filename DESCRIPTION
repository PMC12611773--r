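Package: alignsim
Title: Human-Aligned Similarity Distillation for Triplet Odd-One-Out Judgements
Version: 0.1.0
Authors@R:
    person("alignsim", "maintainers", email = "alignsim@example.org",
           role = c("aut", "cre"))
Description: Toolkit for representational alignment research built around the
    triplet odd-one-out task.  Simulates hierarchically organized concept
    spaces and noisy annotators, fits a variational per-item concept embedding
    that captures human response uncertainty, learns a human-aligned affine
    transform of a teacher embedding space by distilling soft triplet-choice
    distributions, samples cluster-boundary triplet datasets with teacher
    pseudo-labels, fine-tunes student encoders with a temperature-scaled KL
    objective and weight decay to initialization, and evaluates alignment with
    odd-one-out accuracy, representational similarity analysis, entropy-latency
    correlations, leave-one-out noise ceilings and hierarchical
    distance-change contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
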