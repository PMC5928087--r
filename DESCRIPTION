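Package: bcdissect
Title: Virtual Microdissection and Cohort Comparison for Breast Cancer Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements, as a tested and reusable pipeline, the computational
    procedures used to compare two breast-cancer tumor cohorts from bulk
    multi-omics data: intrinsic-subtype calling by per-marker Gaussian mixture
    models with immunohistochemistry priors and consensus voting; 96-channel
    mutational-signature refitting with homologous-recombination-deficiency
    calling; virtual microdissection of bulk expression by non-negative matrix
    factorization with exemplar-gene extraction and tissue-compartment
    attribution; permutation-based attribution of differentially expressed
    genes and pathways to tissue compartments; and bootstrap elastic-net
    variable-usage analysis. A seeded synthetic-compendium generator emulates
    the multi-group data structure (two tumor cohorts, adjacent and healthy
    normal tissue, cell lines) that the downstream stages assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
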