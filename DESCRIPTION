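Package: metabochem
Title: Chemical Organization of Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the chemical basis of metabolic network
    topology. Reconstructs substrate-product networks from reaction lists
    with currency-metabolite, macromolecule and R-group screening; fits
    power-law degree distributions; computes an open polarity/solubility
    descriptor panel (Crippen-type logP, charged-partial-surface-area family,
    ESOL solubility, substructure counts) from SMILES via OpenBabel; runs the
    degree-vs-chemistry statistics (group means with standard errors,
    Kruskal-Wallis and Mann-Whitney tests, binned correlations, early/late
    metabolome classification); models metabolite concentrations by stepwise
    multiple linear regression and epsilon-SVR with leave-one-out cross
    validation, grid search and descriptor-deletion importance; and simulates
    concentration-governed network growth that reproduces scale-free degree
    distributions. Includes seeded synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab
SystemRequirements: OpenBabel (the obabel command-line tool)
Config/testthat/edition: 3
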