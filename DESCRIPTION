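Package: corekit
Title: Core Collection Selection, Population Genomics and Breeding
    Fingerprints for Crop Germplasm Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for SNP-based germplasm panel analysis in crop
    collections: greedy core-collection selection by allele-state
    coverage with breeding-priority seeding, windowed nucleotide
    diversity and Weir-Cockerham FST, linkage-disequilibrium decay and
    half-decay distance, genomic relationship matrices and PCA,
    identity-by-state neighbour-joining trees, Shannon-Wiener diversity
    and broad-sense heritability of ordinal horticultural traits,
    association scans with principal-component covariates, significance
    thresholds, genomic inflation, multi-year BLUPs and QTL clumping,
    and parental-origin fingerprint (bin) maps for biparental progeny.
    Includes seeded simulators for structured diploid populations,
    ordinal traits with target heritability, and selfed biparental
    crosses so every stage can be validated against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    lme4,
    stats,
    utils,
    vcfR,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
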