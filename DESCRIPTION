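Package: orthometa
Title: Cross-Species Meta-Analysis of Differential Expression with
    Ortholog and In-Paralog Support
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Combines per-gene differential-expression p-values across
    species whose genes are linked by many-to-many homology groups
    (orthologs and in-paralogs, e.g. Homologene or OrthoMCL clusters).
    The cross-species score takes the most significant p-value per
    species, de-biases it with a reciprocal harmonic-number paralog
    weight, and sums across experiments with arbitrary non-negative
    weights; its null distribution is a weighted sum of unit
    exponentials approximated by a moment-matched Gamma law (exact in
    the classical Fisher case of one gene per species). Includes
    parsers and generators for homology structures, the three
    previously suggested in-paralog reduction baselines (combined,
    average, random observations followed by Fisher's combined
    probability test), and a reproducible power and false-discovery-rate
    simulation benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
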