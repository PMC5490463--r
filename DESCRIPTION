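Package: paleoclad
Title: Parsimony, Stratigraphic Congruence and Body-Size Estimation for
    Fossil Morphological Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cladistic analysis of discrete morphological
    character matrices with an emphasis on fossil taxa. Implements
    unordered (Fitch) parsimony scoring, exact branch-and-bound and
    random-addition heuristic tree searches, ensemble consistency and
    retention indices, ACCTRAN ancestral-state optimization with
    synapomorphy mapping, homoplasy screening of candidate characters
    against reference trees, the stratigraphic consistency index with
    ghost-lineage and minimum divergence-date estimation, a
    stratocladistic ancestor-descendant test based on parsimony debt,
    and multi-equation allometric body length and mass estimation from
    skull measurements. Includes a seeded synthetic-data generator
    (trees, Mk characters, fossil ranges, measurements) so every stage
    of the pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
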