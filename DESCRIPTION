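Package: kindred
Title: Family-Based Rare-Variant Prioritization for Oligogenic Inheritance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-aware prioritization of rare variants from multi-sample
    exome VCFs. Implements a quality/region/consequence/frequency/predictor
    filter cascade with per-individual stage accounting, four inheritance-model
    segregation filters (autosomal recessive, autosomal dominant, compound
    heterozygous, and a shared-rare "complex" model), a multi-gene candidate-set
    search with a per-affected homozygosity requirement, joint population
    co-occurrence frequency arithmetic, and a gene-drop simulator that
    generates pedigree-consistent synthetic cohorts with per-variant truth
    labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
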