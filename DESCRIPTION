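Package: reclethal
Title: Population Genetics of Recessive Lethal Disease Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models the population frequencies of mutations causing recessive,
    lethal Mendelian diseases. Provides closed-form mutation-selection-balance
    theory for infinite and finite constant-size populations, a forward
    Wright-Fisher simulator of bi-allelic sites (and gene-level pooled lethal
    alleles allowing compound heterozygosity) under mutation, selection,
    migration and drift in a rescaled two-population out-of-Africa demographic
    model, an analytic and simulation-based model of disease-mutation
    ascertainment bias under inbreeding, resampling-based comparison statistics
    between observed variant catalogs and simulated expectations, and a
    generator of synthetic exome-style variant catalogs with CpG/non-CpG
    mutation-rate classes and quality-control filters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
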