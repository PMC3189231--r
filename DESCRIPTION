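Package: pedcnvseg
Title: Co-Segregation Analysis of Copy Number Variants in Extended Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies copy number variants (CNVs) that co-segregate with a
    phenotype in extended multiplex families. Starting from PennCNV-style
    per-sample call files, PED pedigrees and control/population CNV tables, the
    pipeline applies sample- and call-level quality control, detects CNV regions
    shared by every genotyped affected relative in a family (50% reciprocal
    overlap matching), excludes variants carried by multiple married-in
    individuals or inconsistent with descent from a single introducing ancestor,
    filters on ancestry-matched control carrier frequency, and prioritizes the
    surviving candidates by population absence and literature overlap. Includes
    recursive kinship/expected-sharing computation, transmission-path inference,
    the supporting exact and rank-based statistics, and a seeded gene-dropping
    simulator of extended-family cohorts with incomplete penetrance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
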