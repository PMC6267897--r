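test_that("Welch test matches the hand-computed textbook values", {
  res <- welch_t_test(c(0.10, 0.15, 0.20, 0.12), c(0.01, 0.03, 0.02, 0.04))
  # frozen from the independent oracle (see helper-oracles.R)
  expect_equal(res$t_statistic, 5.17976442651305, tolerance = 1e-10)
  expect_equal(res$df, 3.52456238325406, tolerance = 1e-10)
  expect_equal(res$p_value, 0.00926595331486, tolerance = 1e-9)
  expect_equal(res$significance_code, "**")
})

test_that("Welch test agrees with the brute-force oracle on random instances", {
  set.seed(19)
  for (i in 1:100) {
    xs <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1), sd = runif(1, 0.2, 2))
    ys <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1), sd = runif(1, 0.2, 2))
    got <- welch_t_test(xs, ys)
    exp <- welch_oracle(xs, ys)
    expect_equal(got$t_statistic, exp$t, tolerance = 1e-10)
    expect_equal(got$df, exp$df, tolerance = 1e-10)
    expect_equal(got$p_value, exp$p, tolerance = 1e-10)
  }
})

test_that("Welch test handles degenerate and symmetric inputs", {
  expect_error(welch_t_test(c(1, 1, 1), c(2, 2, 2)),
               class = "pyroase_degenerate_variance")
  ident <- welch_t_test(c(0, 0, 0), c(0, 0, 0))
  expect_equal(ident$t_statistic, 0)
  expect_equal(ident$p_value, 1)
  same <- welch_t_test(1:4, 1:4)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t_test(1, 1:3), class = "pyroase_insufficient_sample")
  # swapping groups negates t and preserves p
  a <- rnorm(6); b <- rnorm(8, 1)
  r1 <- welch_t_test(a, b); r2 <- welch_t_test(b, a)
  expect_equal(r1$t_statistic, -r2$t_statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("significance codes use strict thresholds, most stringent first", {
  expect_equal(significance_code(c(0.0009, 0.001, 0.009, 0.01, 0.049, 0.05, 0.9)),
               c("***", "**", "**", "*", "*", "ns", "ns"))
})

test_that("cDNA-vs-gDNA test neutralizes both groups when asked", {
  gd <- c(0.95, 1.02, 1.05, 0.98, 1.01)
  cd <- c(2, 0.5, 1.8, 0.55, 1.9) # bi-directional: raw logs cancel
  raw <- test_cdna_vs_gdna(cd, gd, neutralize_first = FALSE)
  neu <- test_cdna_vs_gdna(cd, gd, neutralize_first = TRUE)
  expect_true(neu$p_value < raw$p_value) # magnitude signal survives neutralization
  expect_equal(neu$mean1, mean(log10(pmax(cd, 1 / cd))))
  ident <- test_cdna_vs_gdna(gd, gd)
  expect_equal(ident$p_value, 1)
  expect_equal(ident$t_statistic, 0)
})

test_that("power of the cDNA-vs-gDNA test grows with effect and n", {
  grid <- expand.grid(fold = c(1.1, 1.3, 1.6), n = c(8, 14, 30))
  rates <- mapply(function(f, n) {
    mean(vapply(1:60, function(i) {
      sim_cdna_gdna_p(seed = 5000 + 97 * i, fold = f, n = n)
    }, numeric(1)) < 0.05)
  }, grid$fold, grid$n)
  power <- matrix(rates, nrow = 3, dimnames = list(fold = NULL, n = NULL))
  # non-decreasing in |effect| at each n, and in n at each effect
  for (j in 1:3) expect_true(all(diff(power[, j]) >= 0))
  for (i in 1:3) expect_true(all(diff(power[i, ]) >= 0))
  expect_true(power[3, 3] > power[1, 1])
})

test_that("directionality reflects which alleles are over-expressed", {
  one <- classify_directionality(c("ase_allele1", "ase_allele1", "balanced"))
  expect_equal(one$value, "one_directional")
  expect_equal(c(one$n_ase_allele1, one$n_ase_allele2), c(2, 0))
  bi <- classify_directionality(c("ase_allele1", "ase_allele2"))
  expect_equal(bi$value, "bi_directional")
  none <- classify_directionality(rep("balanced", 3))
  expect_equal(none$value, "none")
  expect_error(classify_directionality(character()), class = "pyroase_empty_group")
})

test_that("only breeds with enough reporter-SNP heterozygotes are informative", {
  g <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:25),
    breed = rep(c("PLW", "PL"), c(13, 12)),
    gene = "PPARGC1A",
    genotype = c(rep("A/T", 10), rep("A/A", 3),   # PLW: 10 hets
                 rep("A/T", 9), rep("T/T", 3)))   # PL: 9 hets
  inf <- filter_informative_groups(g, min_het = 10)
  expect_true(inf$retained[inf$breed == "PLW"])
  expect_false(inf$retained[inf$breed == "PL"])
  expect_equal(inf$n_het[inf$breed == "PL"], 9)
  empty <- filter_informative_groups(g[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("heterozygote detection tolerates separators and missing calls", {
  expect_equal(is_heterozygous(c("A/T", "A|T", "AA", "T/T", ".", NA)),
               c(TRUE, TRUE, FALSE, FALSE, NA, NA))
})

test_that("phase correction re-orients heterozygote ratios and is involutive", {
  expect_equal(phase_correct(0.2, "het", "cis_ref"), 0.2)
  expect_equal(phase_correct(0.2, "het", "cis_alt"), -0.2)
  expect_equal(phase_correct(0.2, "hom_ref", "unknown"), 0.2)
  expect_error(phase_correct(0.2, "het", "unknown"),
               class = "pyroase_unphased_record")
  # correcting twice under cis_alt returns the original value
  x <- rnorm(20)
  g <- rep("het", 20)
  ph <- rep("cis_alt", 20)
  twice <- phase_correct(phase_correct(x, g, ph), g, ph)
  expect_equal(twice, x)
})

test_that("phase-corrected hets separate from homs when the candidate drives ASE", {
  cfg <- sim_config(seed = 88, breeds = c(SIM = 60L), tissues = "visceral_fat",
                    rsnp_het_fraction = 1,
                    candidate_snp = list(ld_r2 = 1, causal_fold = 1.8),
                    methylation = NULL)
  sim <- simulate_cohort(cfg)
  q <- quantify_sim(sim)
  d <- sim$diplotypes
  d$log10_ratio <- log10(as.numeric(q$cdna[d$sample_id]))
  het <- d$candidate_genotype == "het"
  corrected <- phase_correct(d$log10_ratio[het], d$candidate_genotype[het],
                             d$phase[het])
  # hets center on +log10(causal fold), homs on 0
  expect_equal(mean(corrected), log10(1.8), tolerance = 0.05)
  expect_lt(abs(mean(d$log10_ratio[!het])), 0.05)
  res <- test_variant_association(d)
  expect_lt(res$p_value, 0.001)
})

test_that("variant association handles identical groups and sparse input", {
  d <- tibble::tibble(
    log10_ratio = rep(0.1, 6),
    candidate_genotype = rep(c("het", "hom_ref"), each = 3),
    phase = rep(c("cis_ref", "unknown"), each = 3))
  res <- test_variant_association(d)
  expect_equal(res$p_value, 1)
  expect_error(test_variant_association(d[d$candidate_genotype == "het", ]),
               class = "pyroase_insufficient_sample")
})

test_that("summary table mirrors breed x tissue layout with gDNA anchor", {
  set.seed(3)
  mk <- function(breed, tissue, material, ratios) {
    tibble::tibble(breed = breed, tissue = tissue, material = material,
                   normalized_ratio = ratios)
  }
  ratios <- dplyr::bind_rows(
    mk("PLW", "visceral_fat", "cDNA", 10^rnorm(14, 0.18, 0.1)),
    mk("PLW", "subcutaneous_fat", "cDNA", 10^rnorm(14, 0.02, 0.04)),
    mk("PLW", "blood", "gDNA", 10^rnorm(14, 0, 0.02)))
  out <- aggregate_summary_table(ratios)
  expect_setequal(names(out$table), c("breed", "subcutaneous_fat",
                                      "visceral_fat", "gDNA"))
  vis <- out$cells[out$cells$tissue == "visceral_fat", ]
  gd <- out$cells[out$cells$tissue == "gDNA", ]
  expect_gt(vis$mean_log10, gd$mean_log10)
  expect_true(vis$significance_code %in% c("*", "**", "***"))
  # five-number summaries cover every group
  expect_setequal(out$five_number$group,
                  c("subcutaneous_fat", "visceral_fat", "gDNA"))
  # row-order invariance
  shuffled <- ratios[sample(nrow(ratios)), ]
  out2 <- aggregate_summary_table(shuffled)
  expect_equal(out$cells, out2$cells)
  # all-balanced input gives zero cells, no significance
  flat <- dplyr::bind_rows(mk("PLW", "visceral_fat", "cDNA", rep(1, 5)),
                           mk("PLW", "blood", "gDNA", rep(1, 5)))
  out3 <- aggregate_summary_table(flat)
  expect_true(all(out3$cells$mean_log10 == 0))
  expect_true(all(out3$cells$significance_code[!is.na(out3$cells$significance_code)] == "ns"))
  # log-mean arithmetic
  one <- dplyr::bind_rows(mk("B", "t", "cDNA", c(10^0.1, 10^0.3)),
                          mk("B", "blood", "gDNA", c(1, 1)))
  cell <- aggregate_summary_table(one, neutralize_first = FALSE)$cells
  expect_equal(cell$mean_log10[cell$tissue == "t"], 0.2)
  # missing gDNA cannot anchor
  expect_error(aggregate_summary_table(mk("B", "t", "cDNA", c(1, 1.2))),
               class = "pyroase_cannot_anchor")
})
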