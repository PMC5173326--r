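Package: pubcanon
Title: Publication Bias and the Canonization of Scientific Claims
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the community-level dynamics by which repeatedly tested
    scientific claims come to be accepted as fact or discarded as false when
    negative results are published at a lower rate than positive ones. Belief
    in a claim evolves as a log-odds random walk with absorbing evidentiary
    thresholds; the package computes exact canonization and rejection
    probabilities by dynamic programming over the publication lattice,
    cross-checks them with a seeded Monte-Carlo simulator of the
    experiment-publication process, and provides parameter sweeps (negative
    publication rate, prior belief, evidentiary standards, p-hacking,
    belief-linked publication policies) with CSV/JSON output and a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
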