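Package: mhctyper
Title: MHC Class II Genotyping from Cloned Amplicon Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterises diversity at a classical MHC class II locus
    (DQB exon 2) from cloning-and-Sanger amplicon data: allele calling
    from clone sequences with PCR-artifact filtering, Mendelian quality
    control of mother-offspring pairs, codon-partitioned selection tests
    (modified Nei-Gojobori dN/dS with Jukes-Cantor correction and
    codon-based Z-tests), colony-level population genetics at the MHC and
    at microsatellites (Weir-Cockerham FST with permutation tests,
    diversity summaries, Queller-Goodnight relatedness, standardised
    multilocus heterozygosity), UniFrac distances between individual
    allele sets on a neighbour-joining allele tree with mixed-model
    association tests, and primer-binding-site mismatch analyses with
    bootstrap allele-detection curves. Includes a synthetic-data module
    that generates allele pools, pedigreed genotypes and clone libraries
    with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    BiocGenerics,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
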