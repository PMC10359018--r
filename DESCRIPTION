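Package: seqmut
Title: Mutant Cell Numbers and Arrival Times in Exponentially Growing Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Limit laws for sequential mutation acquisition in exponentially
    growing cell populations modelled as a multitype branching process along a
    linear mutational path. Computes the Mittag-Leffler law of the random
    amplitude of type-n cell numbers and the logistic law of type-n arrival
    times for arbitrary division, death, and mutation rate sequences; provides
    exact, hybrid (tau-leaping), and limit-model stochastic simulators to
    validate the laws; and applies them to mutation-rate inference in
    n-mutation fluctuation assays via the p0 method and a mutant-count
    maximum-likelihood method.
License: MIT
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
    optparse,
    yaml
Config/testthat/edition: 3
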