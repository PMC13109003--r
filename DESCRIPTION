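Package: separisk
Title: Separable and Controlled Direct Effects with Competing Events
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analyses of competing-events data in which the causal
    question concerns a direct treatment effect on the event of interest.
    Distinguishes three compounding error sources when competing events are
    censored although the actual target is a separable direct effect:
    estimand error (controlled versus separable direct effect), structural
    non-identification error from unmeasured common causes of the two event
    processes, and statistical error. Provides exact computation of causal
    and observed-data targets under a fully parameterized point-treatment
    data-generating process, the inverse-probability-of-censoring-weighted
    estimator and the separable-effect weighted estimator with weight
    diagnostics, a Monte Carlo engine comparing their variances under near
    violations of positivity, and discrete-time (pooled logistic)
    generalizations of both estimators with bootstrap percentile intervals
    for trial reanalyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
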