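Package: sbgevol
Title: Evolution of Sex-Biased Gene Expression Across Sex Chromosome Turnovers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studying the evolution of sex-biased
    gene (SBG) expression across closely related species carrying different
    XY sex chromosome systems. Provides sex-bias calling from RNA-seq counts
    (TMM normalization, a negative-binomial Wald test, bias categories),
    intersex population-genetic statistics (Hudson Fst as a per-gene ratio
    of sums, coverage-corrected nucleotide diversity, Tajima's D, site
    frequency spectra), sequence- and expression-level selection statistics
    (Nei-Gojobori dN/dS, the standardized expression-shift statistic delta-x),
    expression phylogenies from 1 - Spearman rho distances with gene
    bootstraps and Robinson-Foulds comparison to the species tree, equal-rates
    Mk ancestral reconstruction of sex-bias states with branch-wise turnover
    counting, phylogenetic GLS trait association, per-linkage-group enrichment
    tests, and a fully labelled synthetic-data generator that emulates the
    study design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    nlme,
    edgeR,
    vcfR,
    seqinr,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
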