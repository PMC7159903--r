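Package: pangevo
Title: Pangenome Structure, Biogeographic Enrichment, and Selection
    Analysis for Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Pangevo", "Developers", email = "pangevo@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the evolution of a bacterial pangenome
    recovered as metagenome-assembled genomes (MAGs) from two environments.
    Builds gene-cluster presence/absence matrices and frequency spectra,
    asymmetric gene-content containment and genome dendrograms, rarefaction
    curves, and a completeness-aware Monte Carlo posterior for core-gene
    membership. Scores per-cluster biogeographic enrichment between two site
    groups with an exact binomial cumulative distribution function, tests
    COG-category composition against a nonparametric permutation null,
    computes per-ORF pN/pS ratios from single-codon variants with
    Nei-Gojobori style potential-site normalization, and detects
    gene-specific selective sweeps as Poisson SNV deficits on contigs.
    Includes a synthetic-data generator that emulates the statistical
    structure of such datasets so every stage is testable without external
    downloads, and a command-line interface chaining the pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
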