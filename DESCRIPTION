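Package: ploidyStrata
Title: Phylostratigraphic Analysis of Polyploidy-Associated Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to isolate a polyploidy-specific transcriptional signature
    from a reciprocal cross-species "criss-cross" factorial design (two species
    by two tissues with inverted ploidy), confirm it by principal component
    analysis, and characterise the resulting gene lists: evolutionary-age
    (phylostratum) shift tests, bivalent-chromatin gene-set enrichment,
    ontology/pathway enrichment with ancestor propagation, and
    protein-interaction network connectivity summaries. Includes a synthetic
    data generator with planted ploidy effects, stratum-dependent effect signs
    and bivalency enrichment so every stage can be validated against known
    ground truth, plus a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
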