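#!/usr/bin/env Rscript
# Simulates the default study-like cohort: four pig breeds (51/35/38/21
# animals), an A/T reporter SNP at heterozygote fraction 0.4, incorporation
# bias 1.1, lognormal per-animal cis fold (SD 0.13 log10) in three tissues,
# duplicate pyrosequencing measurements with beta noise, and per-CpG
# methylation at two 5'-flanking islands with a +3-point shift at the
# designated sites of ASE samples. Writes the measurement, genotype and
# methylation tables plus ground truth under results/sim/.

library(pyroASE)

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20181)
sim <- simulate_cohort(cfg)

write_pyro_tsv(sim$measurements, file.path(out, "measurements.tsv"))
write_pyro_tsv(sim$genotypes, file.path(out, "genotypes.tsv"))
write_pyro_tsv(sim$methylation, file.path(out, "methylation.tsv"))
jsonlite::write_json(
  list(assay = sim$truth$assay,
       animals = sim$truth$animals,
       per_tissue = sim$truth$per_tissue),
  file.path(out, "ground_truth.json"),
  dataframe = "rows", auto_unbox = TRUE, digits = NA)

n_het <- sum(sim$truth$animals$rsnp_het)
cat(sprintf("cohort: %d animals, %d reporter-SNP heterozygotes\n",
            nrow(sim$truth$animals), n_het))
cat(sprintf("measurement rows: %d (duplicates over %d samples x materials)\n",
            nrow(sim$measurements), nrow(sim$measurements) / cfg$n_replicates))
cat(sprintf("true ASE fraction by tissue:\n"))
print(tapply(sim$truth$per_tissue$ase_true, sim$truth$per_tissue$tissue, mean))
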