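Package: fishpopgen
Title: Population Genetics of River Fishes from mtDNA Sequences and
    Polyploid Microsatellite Band Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for phylogeographic and demographic analysis of
    riverine fish populations combining mitochondrial DNA sequence data
    with dominant (band-phenotype) microsatellite data from polyploid
    genomes. Implements haplotype collapsing and site classification,
    diversity indices (haplotype diversity, nucleotide diversity, Kimura
    two-parameter distances), hierarchical analysis of molecular variance
    (AMOVA) with permutation tests, mismatch distributions with
    sudden-expansion model fitting and expansion-time dating, Fu's Fs
    neutrality test via the Ewens sampling formula, median-joining
    haplotype networks, band-based diversity and distance statistics for
    tetraploid microsatellites (PPL, Nei's gene diversity, Shannon index,
    Nei's unbiased distance, principal coordinates, Evanno delta-K), Mantel
    tests of isolation by distance, a coalescent simulator with
    piecewise-constant population size, and a config-driven analysis
    pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
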