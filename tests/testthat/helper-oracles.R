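# Independent oracles and lean simulation drivers shared across test files.

# Textbook Welch statistic, Welch-Satterthwaite df and two-sided p, written
# from the formulas; independent of the pipeline's welch_t_test().
welch_oracle <- function(xs, ys) {
  n1 <- length(xs)
  n2 <- length(ys)
  v1 <- sum((xs - mean(xs))^2) / (n1 - 1)
  v2 <- sum((ys - mean(ys))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(xs) - mean(ys)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Quantify a simulated cohort's single gene/tissue with the package's ratio
# arithmetic (compute -> bias -> normalize -> replicate mean) without the
# full table machinery, for Monte-Carlo loops.
quantify_sim <- function(sim) {
  m <- sim$measurements
  raw <- compute_ratio(m$pct_allele1, m$pct_allele2)
  bias <- estimate_gdna_bias(raw[m$material == "gDNA"])
  norm <- normalize_ratio(raw, bias)
  is_cd <- m$material == "cDNA"
  list(
    cdna = tapply(norm[is_cd], m$sample_id[is_cd], mean),
    gdna = tapply(norm[!is_cd], m$sample_id[!is_cd], mean),
    bias = bias)
}

# One null/power replicate: simulate n heterozygotes at a point-mass fold,
# quantify, and Welch-test log10 cDNA vs gDNA ratios. Point-fold scenarios
# are one-directional, so per the pipeline's per-gene rule neutralization
# stays off (the folded variant is slightly anticonservative at small n).
sim_cdna_gdna_p <- function(seed, fold = 1, n = 14, noise = 300, bias = 1.1,
                            neutralize_first = FALSE) {
  cfg <- sim_config(seed = seed, breeds = c(SIM = as.integer(n)),
                    tissues = "visceral_fat", rsnp_het_fraction = 1,
                    assay_bias_b = bias,
                    cis_fold_distribution = list(type = "point", fold = fold),
                    noise_concentration = noise, methylation = NULL)
  q <- quantify_sim(simulate_cohort(cfg))
  test_cdna_vs_gdna(q$cdna, q$gdna, neutralize_first = neutralize_first)$p_value
}

# One variant-association replicate: candidate SNP at LD r2 with the causal
# driver (r2 = 0 is the null), phase-corrected het-vs-hom Welch test.
sim_variant_p <- function(seed, ld_r2, causal_fold = 1.8, n = 20) {
  cfg <- sim_config(seed = seed, breeds = c(SIM = as.integer(n)),
                    tissues = "visceral_fat", rsnp_het_fraction = 1,
                    candidate_snp = list(ld_r2 = ld_r2, causal_fold = causal_fold),
                    methylation = NULL)
  sim <- simulate_cohort(cfg)
  q <- quantify_sim(sim)
  d <- sim$diplotypes
  d$log10_ratio <- log10(as.numeric(q$cdna[d$sample_id]))
  n_het <- sum(d$candidate_genotype == "het")
  if (n_het < 2 || nrow(d) - n_het < 2) return(NA_real_)
  test_variant_association(d)$p_value
}

# Small fat-tissue-like replicate measurement table built by hand.
toy_measurements <- function() {
  tibble::tibble(
    sample_id = rep(c("s1", "s1", "s2", "s2"), times = 2),
    breed = "PLW",
    tissue = rep(c("visceral_fat", "blood"), each = 4),
    gene = "PPARGC1A",
    material = rep(c("cDNA", "gDNA"), each = 4),
    allele1 = "A", allele2 = "T",
    pct_allele1 = c(60, 62, 45, 44, 51, 52, 50, 49),
    pct_allele2 = c(40, 38, 55, 56, 49, 48, 50, 51),
    replicate = rep(c(1L, 2L), times = 4))
}
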