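Package: meiosim
Title: Stochastic Simulation of Breeding Programs on Real or Synthetic
    Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scripting toolkit for stochastic simulation of crossing and
    selection in diploid breeding programs, starting from real or synthetic
    founder genotypes on a centimorgan linkage map. Meiosis is simulated by
    the count-location method (Poisson crossover counts sized by map length
    in Morgans, uniformly placed crossovers, no interference), with full
    tracking of linkage phase. Offspring are produced by targeted crosses,
    random crosses, selfing, and doubled haploidy; every genotype belongs to
    a group, and groups can be split, merged, and truncation-selected on
    additive breeding values or on phenotypes masked at a chosen broad-sense
    heritability. Includes population-genetic summaries (Rogers' genetic
    distance, linkage-disequilibrium r-squared decay) and packaged scenarios
    for a cyclic phenotypic-selection program and a nested association
    mapping (NAM) population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
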