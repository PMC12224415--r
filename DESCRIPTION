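Package: idoct
Title: Iterative Decomposition of Cognitive-Task Timecourses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes trial-by-trial reaction-time and accuracy timecourses
    from computerised cognitive tasks into data-driven trial difficulty,
    participant cognitive ability, and visuo-motor delay, via a two-stage
    fixed-point iteration (IDoCT). Includes frozen-parameter rescoring of
    follow-up sessions with test-retest reliability summaries, a synthetic
    adaptive picture-vocabulary-task simulator with known latent parameters
    for parameter-recovery validation, diagnostic views of difficulty
    sampling trajectories, and a ranked drop-lowest stepwise feature-selection
    pipeline with cross-validated model choice and eta-squared attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    e1071,
    optparse
Config/testthat/edition: 3
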