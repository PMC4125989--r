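Package: adnakit
Title: Low-Coverage Ancient DNA Screening: Damage, Sex, Ancestry and
    Mitochondrial Haplogroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for screening low-coverage historical and ancient DNA
    sequencing data. Estimates terminal cytosine-deamination damage profiles
    and per-read post-mortem degradation (PMD) scores for contamination
    filtering; assigns genetic sex from X/Y read counts via the Ry statistic
    with binomial confidence intervals; produces pseudo-haploid genotype
    calls at reference-panel SNPs; places sparse samples into a reference
    principal-component space by per-sample Procrustes projection; fits
    admixture proportions by a monotone binomial EM with cross-validation
    and CLUMPP-style alignment of repeated runs; and scores mitochondrial
    haplogroups against a defining-mutation tree. A seeded synthetic-data
    generator (Balding-Nichols panels, damaged low-coverage fragments,
    sex-chromosome read counts, mitochondrial fragments) makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
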