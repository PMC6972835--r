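Package: sirepart
Title: Exclusion-Based Paternity and Mating-System Analysis for Sequential Clutches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parentage analysis for species in which a known mother lays several
    clutches per season and a sample of offspring is genotyped at a multilocus
    microsatellite panel. Subtracts the maternal contribution from each
    hatchling genotype, partitions hatchlings into paternal sibships by an
    exact minimum-father search, calls multiple paternity under the
    three-alleles-at-two-loci rule, matches reconstructed sires across clutches
    and females, and classifies father turnover between clutches as sperm
    storage/depletion versus remating. Includes locus-quality statistics
    (heterozygosity, Monte-Carlo Hardy-Weinberg tests, probability of identity
    and of exclusion), breeding-sex-ratio estimation with population
    extrapolation, nest-inventory and carapace-morphometry utilities, and a
    seeded synthetic-data generator so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
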