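Package: aluvar
Title: Discovery, Local Assembly, Breakpoint Resolution and Genotyping of
    Non-Reference Alu Insertions
Version: 0.1.0
Authors@R:
    person("aluvar", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing polymorphic Alu mobile-element
    insertions from paired-end short-read data: anchored discordant-pair
    discovery, per-site greedy overlap-layout-consensus assembly,
    breakpoint and target-site-duplication resolution by scored three-way
    alignment, subfamily classification against a consensus profile, and
    MAPQ-based genotype likelihoods with ploidy-aware EM allele frequency
    estimation under Hardy-Weinberg equilibrium. Includes a synthetic-data
    generator (toy genomes, L1-endonuclease-motif rejection-sampled
    insertion sites, implanted elements with TSDs, poly-A tails and 5'
    truncations, and simulated paired-end reads) so that every pipeline
    stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
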