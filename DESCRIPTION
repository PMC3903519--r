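Package: snpcycle
Title: Network Phenotyping of Multilocus SNP Genotypes via k-Partite Graph Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes each subject's multilocus SNP genotype as a closed path
    (cycle) through a k-partite graph with one allele-state partition per
    locus, accumulates a cohort of such cycles into a weighted study graph,
    and greedily decomposes that graph into equal-weight reference cycles
    whose multiplicities act as haplotype frequencies. Per-subject
    edge-mismatch distances from the reference cycles, and their pairwise
    differences, form a feature space for case/control discrimination and
    for survival-threshold analysis. Includes an expectation-maximization
    haplotype frequency estimator under Hardy-Weinberg equilibrium as an
    independent cross-check, and a seeded synthetic-cohort generator for
    diplotypes drawn from a haplotype pool with strong linkage
    disequilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    withr,
    rpart,
    pROC,
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
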