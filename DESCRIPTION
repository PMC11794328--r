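Package: phenodrug
Title: Phenotype-Drug Association via Tripartite Network Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts associations between pathological phenotypes (HPO
    terms) and drugs by projecting tripartite phenotype-target-drug
    networks. Phenotype-target and drug-target layers are scored with a
    hypergeometric overlap index (-log10 of the upper-tail probability of
    the observed shared-neighbour count); targets can be proteins or CATH
    functional families (FunFams), the latter derived by binomial
    overrepresentation among a drug's filtered ChEMBL-style targets.
    Predictions are benchmarked against a gold-standard effect list and
    literature co-mention counts using degree-preserving link
    randomization nulls. Includes a deterministic synthetic-universe
    generator with planted phenotype-drug signal for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
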