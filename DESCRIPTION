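Package: microgliaLOH
Title: Simulation and Detection of Loss-of-Heterozygosity Microglia in
    Reporter Knock-In Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse the multi-modal evidence by which a
    rare Cx3cr1-wild-type, reporter-negative microglial subpopulation can be
    identified in CreER-Eyfp knock-in mice. Includes toy-scale paired-end
    whole-genome read simulation over a hybrid reference (genome plus knock-in
    cassette contig), duplicate marking and MAPQ filtering, physical
    (fragment-span) coverage, allele-dosage and junction-read zygosity calling,
    in-silico PCR genotyping from primer sequences, skeleton-based microglial
    morphometry with reporter-channel subtraction, optical-fractionator
    stereology with the Schmitz-Hof second coefficient of error, hierarchical
    flow-cytometry gating and subpopulation quantification, RPKM-based
    differential expression with Benjamini-Hochberg correction, and a
    stochastic branching model of mitotic loss of heterozygosity, depletion and
    repopulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
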