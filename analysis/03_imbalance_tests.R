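#!/usr/bin/env Rscript
# Breed x tissue imbalance tests: mean log10 neutralized allelic transcript
# ratios for every breed x tissue cell against the breed's heterozygous
# gDNA, two-tailed Welch t-test, with significance codes — the aggregate
# summary-table view of the cohort. Also prints five-number summaries of
# the normalized ratios per group (the boxplot statistics).

library(pyroASE)

stopifnot(file.exists("results/ase/normalized_ratios.tsv")) # run 02 first

ratios <- tibble::as_tibble(utils::read.delim("results/ase/normalized_ratios.tsv",
                                              na.strings = "."))
summ <- aggregate_summary_table(ratios, neutralize_first = TRUE)

cat("mean log10 neutralized allelic transcript ratio (cDNA vs gDNA Welch test):\n")
print(as.data.frame(summ$table), row.names = FALSE)
cat("\nper-cell detail:\n")
print(as.data.frame(summ$cells), row.names = FALSE)
cat("\nfive-number summaries (normalized ratio):\n")
print(as.data.frame(summ$five_number), row.names = FALSE)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write_pyro_tsv(summ$table, "results/tables/imbalance_summary.tsv")
write_pyro_tsv(summ$five_number, "results/tables/five_number.tsv")
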