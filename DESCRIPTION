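Package: mhcdiv
Title: Functional MHC Supertype Diversity and Population Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of functional diversity at multilocus major
    histocompatibility complex (MHC) amplicons where allele dosage is
    unknown. Clusters alleles into functional supertypes from
    physicochemical z-descriptors of positively selected sites using
    k-means with a BIC elbow rule, tests pairwise allele associations
    with the index of association and permutation p-values, simulates
    null ensembles of artificial genotypes (random or linked assembly)
    and compares observed individual supertype counts to the null with
    a discrete Kolmogorov-Smirnov test, computes per-site diversity
    statistics (allelic richness by rarefaction, segregating sites,
    nucleotide diversity with Nei-Gojobori synonymous/nonsynonymous
    partition), and measures ploidy-independent Rho differentiation
    with Mantel and partial Mantel isolation-by-distance tests. A
    synthetic-data generator with stored ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    vegan,
    permute,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
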