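Package: gcturnover
Title: Gain/Loss Dynamics of GC-Cluster Mobile Elements in Yeast
    Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and evolutionary analysis of short GC-rich
    palindromic elements (GC clusters) that behave as mobile DNA in
    AT-rich yeast mitochondrial genomes. Finds dispersed repeats and
    their target-site duplications in a single genome, maps homologous
    element positions across strains by flank anchoring, and fits a
    two-state continuous-time Markov model of element gain and loss on
    a strain phylogeny by maximum likelihood (Felsenstein pruning),
    with standard errors, likelihood-ratio tests of equal gain and
    loss rates, and marginal ancestral-state reconstruction. Also
    provides hairpin structure partitioning with loop/stem
    substitution enrichment tests, co-conversion tract detection,
    merger and horizontal-exchange classification, and a forward
    simulator of multi-strain genome sets with full truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
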