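Package: somaticfunnel
Title: Somatic Novel-Variant Discovery Funnel for Tumor-Normal Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline re-implementation of a tumor versus matched-normal exome
    somatic-variant discovery workflow: VCF preprocessing (multi-allelic
    decomposition, indel left-normalization), exome quality control (off-target
    counts, Ti/Tv ratio, dbSNP concordance), germline subtraction, an ordered
    database-novelty filter cascade, transcript-model based region and coding
    consequence annotation, Cancer Gene Census comparison, binomial pathway
    over-representation with Benjamini-Hochberg correction, consensus calls
    over functional-impact predictors, and four-parameter-logistic IC50
    estimation for inhibitor screens. Includes seeded synthetic-cohort
    generators that plant variants realizing a prescribed stage-by-stage
    filtering profile, so the whole pipeline is verifiable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    IRanges,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
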