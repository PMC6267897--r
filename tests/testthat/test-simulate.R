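test_that("invalid simulation configs are rejected with the offending fields", {
  expect_error(sim_config(seed = 1, assay_bias_b = -1),
               class = "pyroase_config_error")
  expect_error(sim_config(seed = 1, rsnp_het_fraction = 0),
               class = "pyroase_config_error")
  expect_error(sim_config(seed = 1, cis_fold_distribution = list(type = "cauchy")),
               class = "pyroase_config_error")
  err <- tryCatch(sim_config(seed = 1, assay_bias_b = 0, noise_concentration = -2),
                  error = identity)
  expect_match(conditionMessage(err), "assay_bias_b")
  expect_match(conditionMessage(err), "noise_concentration")
})

test_that("zero-noise limit reproduces the deterministic fraction model", {
  # f = 1, b = 1: everything at 50/50
  cfg <- sim_config(seed = 10, breeds = c(X = 20L), tissues = "visceral_fat",
                    rsnp_het_fraction = 1, assay_bias_b = 1,
                    cis_fold_distribution = list(type = "point", fold = 1),
                    noise_concentration = 1e8, methylation = NULL)
  sim <- simulate_cohort(cfg)
  expect_true(all(abs(sim$measurements$pct_allele1 - 50) <= 0.1))
  # f = 1.5, b = 1: cDNA allele1 at 60%
  cfg2 <- sim_config(seed = 10, breeds = c(X = 20L), tissues = "visceral_fat",
                     rsnp_het_fraction = 1, assay_bias_b = 1,
                     cis_fold_distribution = list(type = "point", fold = 1.5),
                     noise_concentration = 1e8, methylation = NULL)
  m2 <- simulate_cohort(cfg2)$measurements
  expect_true(all(abs(m2$pct_allele1[m2$material == "cDNA"] - 60) <= 0.1))
  expect_true(all(abs(m2$pct_allele1[m2$material == "gDNA"] - 50) <= 0.1))
})

test_that("exported percentages always sum to 100", {
  sim <- simulate_cohort(sim_config(seed = 77))
  expect_true(all(abs(sim$measurements$pct_allele1 +
                        sim$measurements$pct_allele2 - 100) < 1e-9))
  expect_true(all(sim$measurements$pct_allele1 > 0 &
                    sim$measurements$pct_allele1 < 100))
})

test_that("identical config and seed give identical datasets", {
  cfg <- sim_config(seed = 123)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$methylation, s2$methylation)
  s3 <- simulate_cohort(sim_config(seed = 124))
  expect_false(identical(s1$measurements, s3$measurements))
})

test_that("ground truth is consistent with the noise-free expectations", {
  cfg <- sim_config(seed = 15, breeds = c(X = 200L), tissues = "visceral_fat",
                    rsnp_het_fraction = 1, assay_bias_b = 1.2,
                    cis_fold_distribution = list(type = "point", fold = 2),
                    noise_concentration = 1e7, methylation = NULL)
  sim <- simulate_cohort(cfg)
  m <- sim$measurements
  tr <- sim$truth$per_tissue
  b <- sim$truth$assay$bias_b
  expect_equal(b, 1.2)
  # recomputing expected fractions from truth matches the near-noiseless data
  expected_cdna <- 100 * b * tr$true_fold / (1 + b * tr$true_fold)
  cd1 <- m[m$material == "cDNA" & m$replicate == 1, ]
  cd1 <- cd1[match(tr$sample_id, cd1$sample_id), ]
  expect_equal(cd1$pct_allele1, expected_cdna, tolerance = 0.002)
  expect_true(all(tr$ase_true)) # fold 2 exceeds the 60:40 threshold
  expect_true(all(tr$over_allele == "A"))
})

test_that("gDNA ratios recover the generating bias", {
  cfg <- sim_config(seed = 29, breeds = c(X = 500L), tissues = "visceral_fat",
                    rsnp_het_fraction = 1, assay_bias_b = 1.25,
                    cis_fold_distribution = list(type = "point", fold = 1),
                    methylation = NULL)
  m <- simulate_cohort(cfg)$measurements
  gd <- m[m$material == "gDNA", ]
  bias_hat <- estimate_gdna_bias(compute_ratio(gd$pct_allele1, gd$pct_allele2))
  expect_lt(abs(bias_hat / 1.25 - 1), 0.02)
})

test_that("bi-directional mode over-expresses each allele equally often", {
  cfg <- sim_config(seed = 41, breeds = c(X = 1000L), tissues = "visceral_fat",
                    rsnp_het_fraction = 1,
                    cis_fold_distribution = list(type = "two_point", fold = 2),
                    methylation = NULL)
  tr <- simulate_cohort(cfg)$truth$per_tissue
  n_up <- sum(tr$over_allele == "A")
  expect_gt(stats::binom.test(n_up, nrow(tr), 0.5)$p.value, 0.01)
})

test_that("candidate-SNP LD drives phase, genotype and fold jointly", {
  cfg <- sim_config(seed = 61, breeds = c(X = 400L), tissues = "visceral_fat",
                    rsnp_het_fraction = 1,
                    candidate_snp = list(ld_r2 = 1, causal_fold = 2),
                    methylation = NULL)
  sim <- simulate_cohort(cfg)
  d <- sim$truth$candidate
  # perfect LD: candidate hets are exactly the fold != 1 animals
  expect_true(all(xor(d$candidate_genotype == "het", d$true_fold == 1)))
  # phase tells which haplotype carries the high-expressing (ref) allele
  het <- d[d$candidate_genotype == "het", ]
  expect_true(all(het$true_fold[het$phase == "cis_ref"] > 1))
  expect_true(all(het$true_fold[het$phase == "cis_alt"] < 1))
  # unlinked candidate: genotype independent of fold (fold still varies)
  cfg0 <- sim_config(seed = 62, breeds = c(X = 400L), tissues = "visceral_fat",
                     rsnp_het_fraction = 1,
                     candidate_snp = list(ld_r2 = 0, causal_fold = 2),
                     methylation = NULL)
  d0 <- simulate_cohort(cfg0)$truth$candidate
  tab <- table(d0$candidate_genotype == "het", d0$true_fold == 1)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("scenario grids produce a deterministic manifest", {
  grid <- tibble::tibble(cell_id = c("null", "eff"), fold = c(1, 1.5),
                         n_het = c(5L, 5L), noise_concentration = 300,
                         n_datasets = c(1L, 2L))
  man <- simulate_null_and_power_grid(grid, base_seed = 100)
  expect_equal(nrow(man), 3)
  expect_equal(man$seed, c(100L + 10000L + 1L, 100L + 20000L + 1L,
                           100L + 20000L + 2L))
  dup <- dplyr::mutate(grid, cell_id = "same")
  expect_error(simulate_null_and_power_grid(dup, 1),
               class = "pyroase_manifest_error")
  # written datasets are reproduced byte-identically on a second run
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_null_and_power_grid(grid[1, ], base_seed = 100, out_dir = d1)
  simulate_null_and_power_grid(grid[1, ], base_seed = 100, out_dir = d2)
  f1 <- file.path(d1, "null_001.tsv")
  f2 <- file.path(d2, "null_001.tsv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(file.path(d1, "manifest.json")))
})
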