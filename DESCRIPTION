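Package: sickleHaps
Title: Beta-Globin Cluster Haplotyping and Malaria-Variant Population Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico restriction-fragment-length-polymorphism (RFLP)
    haplotyping of the beta-globin gene cluster and population-genetic
    analysis of malaria-associated variants. Provides IUPAC-aware
    restriction-site scanning and fragment prediction, HbS (rs334)
    genotyping by DdeI-site loss, classification of five-site RFLP
    profiles into classical or atypical beta-globin haplotypes,
    allele-frequency and exact Hardy-Weinberg testing, pairwise
    F-statistics and allele-frequency cline trend tests, two-locus EM
    haplotype-frequency estimation with D'/r-squared linkage
    disequilibrium and Gabriel-style haplotype blocks, and haplotype
    bifurcation (EHH) trees around a core variant. A synthetic-data
    generator produces cohorts, sequences and phased panels with the
    statistical structure the analysis assumes, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
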