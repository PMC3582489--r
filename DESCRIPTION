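Package: invexpr
Title: Inversion Genotype Calling and Cis-eQTL Analysis for the 17q21.31 Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs chromosomal-inversion genotypes (H1/H1, H1/H2,
    H2/H2) from a local SNP dosage matrix by EIGENSTRAT-style normalization
    and principal-component clustering with ambiguity exclusion, validates
    calls against Hardy-Weinberg expectations, and tests cis expression
    probes for per-copy allele-dosage effects with covariates under
    Bonferroni control. Includes probe-level artifact checks (common SNPs
    inside the 50-mer probe sequence, ungapped cross-hybridization scans
    against paralog transcripts) and a two-clade haplotype simulator that
    generates genotype and expression cohorts with the statistical
    structure the analysis assumes, so every stage is testable without
    external data.
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
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    Biostrings,
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
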