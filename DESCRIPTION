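Package: pathburden
Title: Rare-Variant Pathway Burden Enrichment for Case-Control Exome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Collapsing burden analysis of rare deleterious variants over
    pathway gene sets in multi-cohort case-control exome studies.
    Qualifies variants by consequence class (stop-gain, start-loss,
    frameshift, canonical splice) and population rarity (gnomAD allele
    count), collapses qualifying carriers to gene- and pathway-level
    indicator matrices, tests per-pathway enrichment of the case cohort
    against each comparison cohort with one-sided Fisher exact tests and
    Benjamini-Hochberg FDR control, and validates enrichment against the
    pooled comparison cohorts with a Monte-Carlo case-label permutation
    null. Includes a seeded synthetic multi-cohort generator (annotated
    VCF, GMT, manifest, truth table) for end-to-end testing, null
    calibration and power analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    parallel,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
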