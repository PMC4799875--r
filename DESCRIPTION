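Package: lvncTriage
Title: Triage of Reported Disease-Variant Associations Against Background
    Population Exomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-evaluates literature-reported disease-associated protein
    variants (left ventricular non-compaction as the worked case) against
    background-population exome stores. Provides a validated variant catalog
    with HGVS p. parsing, presence and allele-frequency lookup in ESP- and
    ExAC-like allele-count stores, a carrier-count plausibility rule, four
    in-silico prediction channels (cross-species conservation, Grantham
    physicochemical distance, SIFT and PolyPhen-2 label adapters) combined by
    a >=3-agreement consensus rule, pedigree-based co-segregation assessment,
    and aggregate reporting. Includes seed-deterministic generators for
    synthetic cohorts, alignment columns, pedigrees and a marginally matched
    study fixture so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: VariantAnnotation, GeneticVariability, Genetics, Software
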