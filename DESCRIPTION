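Package: bsewas
Title: Binomial-Regression EWAS, DMR Calling and cis-meQTL Classification
    for Targeted Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for sequencing-based epigenome-wide association
    studies of whole-blood DNA methylation, modelled on methylC-capture
    sequencing (MCC-Seq) studies of anti-citrullinated protein antibody
    (ACPA) positivity and rheumatoid arthritis. Per-CpG methylated and
    unmethylated read counts are modelled with binomial (logit) regression
    with covariate and measured blood-cell-proportion adjustment; Wald
    tests, Storey q-values and the genomic-control inflation factor are
    computed; significant CpGs are merged into differentially methylated
    regions by a seed-and-merge caller; ordinal ACPA-dose and directional
    analyses, cis-meQTL mapping with genotype-adjusted refits (gDMR/ngDMR
    classification), genomic-feature enrichment and discovery-to-validation
    replication complete the pipeline. A synthetic data generator emulates
    the full study design (counts, sample sheet, genotypes, annotations)
    with known ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
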