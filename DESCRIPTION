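Package: germdiv
Title: Germplasm Diversity Analysis from Phenotypic Traits and SSR Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising crop germplasm collections from
    phenotypic trait tables and codominant SSR (microsatellite) marker data.
    Computes Shannon-Weaver phenotypic diversity indices, coefficients of
    variation and trait correlations; ranks accessions by a principal
    component based comprehensive score and selects representative subsets
    under qualitative-class coverage constraints; derives per-locus and
    per-population genetic diversity statistics (effective allele number,
    observed/expected heterozygosity, Nei's gene diversity, polymorphism
    information content) and Nei (1972) identity and distance between
    populations; builds UPGMA dendrograms from band-sharing distances;
    fits the admixture model by expectation-maximisation with Evanno
    delta-K model selection; and encodes per-accession DNA fingerprints
    and molecular identity payloads. A seeded synthetic-data generator
    produces phenotype and structured genotype matrices with realistic
    diversity properties so every pipeline stage can be exercised without
    access to raw field or gel data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Matrix,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
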