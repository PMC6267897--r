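Package: pyroASE
Title: Allele-Specific Expression Analysis from Pyrosequencing Allele Percentages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies allele-specific expression (ASE) from pyrosequencing
    allele percentages measured at an exonic reporter SNP. Converts allele
    percentages to allelic transcript ratios, corrects per-assay nucleotide
    incorporation bias using heterozygous genomic-DNA controls, averages
    technical replicates, classifies samples against the 60:40 (ratio 1.5 /
    0.667) threshold, and tests cDNA-versus-gDNA imbalance per breed and
    tissue with Welch t tests on log10 ratios. Also tests promoter-variant
    association via phase-corrected within-sample ratios, compares per-CpG
    percent 5-methylcytosine between ASE and balanced groups, and ships a
    seeded synthetic-cohort generator with emitted ground truth for
    parameter-recovery and Monte-Carlo calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
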