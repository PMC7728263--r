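Package: clonerate
Title: Mutability Landscape Inference for Tumor Mutation Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood inference of per-subclone mutation rates
    ("mutability landscapes") from cancer mutation trees derived from
    single-cell sequencing.  Given a rooted mutation tree, the package
    jointly estimates subclone mutation rates, mutation-event times, the
    common sampling time, and the sibling birth orders that resolve the
    tree's polytomies into a timed binary phylogeny.  Includes an EM
    solver with convex event-time optimization, closed-form star-tree
    solutions, a restricted rate-change ("s-model") Metropolis search,
    model selection via Bayes factors and information criteria,
    rate-uncertainty quantification over posterior tree samples, a
    continuous-time birth-process tumor simulator with genotype noise,
    and accuracy metrics for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
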