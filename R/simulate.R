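# Seeded synthetic-cohort generator. Emulates the measurement design of a
# pyrosequencing ASE study: heterozygous reporter-SNP animals across breeds,
# a per-assay nucleotide-incorporation bias acting multiplicatively on
# allelic odds in both cDNA and gDNA, a per-animal cis fold effect shifting
# cDNA allele fractions, beta-distributed replicate noise on measured
# fractions, candidate-SNP haplotypes in configurable LD with the causal
# driver, and per-CpG methylation with a group-level shift in ASE samples.
# Ground truth is emitted alongside every dataset.

#' Default CpG island set for the methylation simulator
#'
#' Two low-methylation 5'-flanking islands mirroring the assayed amplicons
#' of the porcine PPARGC1A region (SSC8 coordinates, 1-based): a handful of
#' CpG sites per island with control-group means in the 2-6% range.
#'
#' @param ase_shift Percentage-point increase applied to ASE-group means at
#'   the designated differential site of each island (default 3).
#' @param noise_sd Per-record normal noise SD in percentage points.
#' @return List of per-island specs (`island`, `mean_ctrl`, `mean_ase`, `sd`).
#' @export
default_methylation_spec <- function(ase_shift = 3, noise_sd = 1) {
  cgi1 <- cpg_island("CGi1", "SSC8", 18527230L, 18528335L,
                     c(18527612L, 18527645L, 18527678L, 18527703L, 18527731L))
  cgi2 <- cpg_island("CGi2", "SSC8", 18524520L, 18526314L,
                     c(18525190L, 18525215L, 18525237L, 18525261L, 18525290L, 18525312L))
  list(
    list(island = cgi1,
         mean_ctrl = c(4, 3.5, 3, 4.5, 4),
         mean_ase = c(4, 3.5, 3 + ase_shift, 4.5, 4),
         sd = noise_sd),
    list(island = cgi2,
         mean_ctrl = c(2.5, 2, 2, 3, 2.5, 2),
         mean_ase = c(2.5, 2 + ase_shift, 2 + ase_shift, 3, 2.5, 2),
         sd = noise_sd))
}

#' Build a validated simulation configuration
#'
#' Defaults describe the study-like scenario: four commercial pig breeds
#' with their cohort sizes, a reporter SNP at intermediate frequency
#' (heterozygote fraction 0.4), a mild incorporation bias of 1.1 on allelic
#' odds, a lognormal per-animal cis fold (SD 0.13 on the log10 scale, which
#' puts roughly 15-25% of fat-tissue samples past the 60:40 threshold),
#' beta noise with concentration 300 on measured fractions, and duplicate
#' technical measurements.
#'
#' @param seed Mandatory integer seed.
#' @param breeds Named integer vector of animals per breed.
#' @param tissues Character vector of cDNA tissues.
#' @param rsnp_het_fraction Probability an animal is heterozygous at the
#'   reporter SNP.
#' @param assay_bias_b Expected gDNA allele1:allele2 odds (incorporation
#'   bias), > 0.
#' @param cis_fold_distribution Per-animal fold spec: `list(type = "point",
#'   fold = )`, `list(type = "lognormal", sdlog10 = )`, or `list(type =
#'   "two_point", fold = , p_allele1 = )` (bi-directional: fold applied to a
#'   randomly chosen numerator allele). Drawn independently per animal x
#'   tissue. Ignored when `candidate_snp` is supplied (the fold then comes
#'   from the causal haplotypes and is constant across tissues).
#' @param noise_concentration Beta precision of measured fractions; larger
#'   is less noisy.
#' @param n_replicates Technical replicates per sample x material (default 2).
#' @param candidate_snp `NULL`, or `list(ld_r2 = , causal_fold = , p_causal
#'   = )`: candidate-variant haplotypes correlated with a causal driver whose
#'   high-expressing allele is aligned with the candidate reference allele;
#'   `ld_r2 = 1` makes the candidate the driver, `ld_r2 = 0` unlinked.
#' @param methylation `NULL` to skip, or a spec list as from
#'   [default_methylation_spec()]; `methylation_tissues` names the tissues
#'   assayed.
#' @param methylation_tissues Tissues with methylation data.
#' @param rsnp_alleles Length-2 character vector, numerator allele first.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       breeds = c(PLW = 51L, PL = 35L, Duroc = 38L, Pietrain = 21L),
                       tissues = c("subcutaneous_fat", "visceral_fat", "l_dorsi_muscle"),
                       rsnp_het_fraction = 0.4,
                       assay_bias_b = 1.1,
                       cis_fold_distribution = list(type = "lognormal", sdlog10 = 0.13),
                       noise_concentration = 300,
                       n_replicates = 2L,
                       candidate_snp = NULL,
                       methylation = default_methylation_spec(),
                       methylation_tissues = c("subcutaneous_fat", "visceral_fat"),
                       rsnp_alleles = c("A", "T")) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(length(seed) == 1 && is.finite(seed), "seed: a single integer is required")
  chk(length(breeds) >= 1 && all(breeds >= 1) && !is.null(names(breeds)),
      "breeds: named counts >= 1 required")
  chk(rsnp_het_fraction > 0 && rsnp_het_fraction <= 1,
      "rsnp_het_fraction: must be in (0, 1]")
  chk(assay_bias_b > 0, "assay_bias_b: must be > 0")
  chk(noise_concentration > 0, "noise_concentration: must be > 0")
  chk(n_replicates >= 1, "n_replicates: must be >= 1")
  chk(is.list(cis_fold_distribution) &&
        cis_fold_distribution$type %in% c("point", "lognormal", "two_point"),
      "cis_fold_distribution: type must be point, lognormal or two_point")
  if (!is.null(candidate_snp)) {
    chk(candidate_snp$ld_r2 >= 0 && candidate_snp$ld_r2 <= 1,
        "candidate_snp$ld_r2: must be in [0, 1]")
    chk(candidate_snp$causal_fold > 0, "candidate_snp$causal_fold: must be > 0")
  }
  chk(length(rsnp_alleles) == 2 && rsnp_alleles[1] != rsnp_alleles[2],
      "rsnp_alleles: two distinct alleles required")
  if (length(problems) > 0) {
    rlang::abort(paste0("invalid simulation config:\n",
                        paste("-", problems, collapse = "\n")),
                 class = "pyroase_config_error")
  }
  structure(list(
    seed = as.integer(seed), breeds = breeds, tissues = tissues,
    rsnp_het_fraction = rsnp_het_fraction, assay_bias_b = assay_bias_b,
    cis_fold_distribution = cis_fold_distribution,
    noise_concentration = noise_concentration,
    n_replicates = as.integer(n_replicates),
    candidate_snp = candidate_snp, methylation = methylation,
    methylation_tissues = methylation_tissues,
    rsnp_alleles = rsnp_alleles), class = "sim_config")
}

# measured allele1 fraction: beta noise around the expected fraction
.draw_fraction <- function(n, expected, concentration) {
  stats::rbeta(n, expected * concentration, (1 - expected) * concentration)
}

# per-animal(-x-tissue) cis fold draw
.draw_fold <- function(n, spec) {
  switch(spec$type,
    point = rep(spec$fold, n),
    lognormal = 10^stats::rnorm(n, 0, spec$sdlog10),
    two_point = {
      p1 <- if (is.null(spec$p_allele1)) 0.5 else spec$p_allele1
      up <- stats::rbinom(n, 1, p1) == 1
      ifelse(up, spec$fold, 1 / spec$fold)
    })
}

#' Simulate a pyrosequencing ASE cohort with ground truth
#'
#' For each reporter-SNP heterozygote the expected measured allele1 fraction
#' is `b / (1 + b)` in gDNA and `b f / (1 + b f)` in cDNA, where `b` is the
#' assay's incorporation bias on allelic odds and `f` the animal's cis fold
#' effect; each replicate's fraction is drawn from a beta distribution with
#' that mean and the configured precision, and reported as percentages
#' summing to 100 (rounded to 0.1 as an instrument would; ground truth
#' keeps full precision). Candidate-SNP genotypes and phase are drawn at the
#' haplotype level to match the configured LD with the causal driver.
#' Per-CpG methylation is drawn normal, truncated to \[0, 100\], with
#' group means keyed on each sample's true ASE status in that tissue.
#'
#' Generation order is fixed (animals, heterozygosity, haplotypes, folds,
#' gDNA, cDNA by tissue, methylation) so identical configs give identical
#' datasets.
#'
#' @param config A [sim_config()].
#' @param gene Assay/gene label stamped on the tables.
#' @return List of tibbles: `measurements` (replicate-level pyro table),
#'   `genotypes` (reporter-SNP genotypes for all animals), `diplotypes`
#'   (candidate-SNP genotype and phase per heterozygote; present when
#'   configured), `methylation` (per-record percent 5-mC; present when
#'   configured), and `truth` (list with per-animal, per-sample-tissue and
#'   assay-level generating parameters).
#' @export
simulate_cohort <- function(config, gene = "PPARGC1A") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  a1 <- config$rsnp_alleles[1]
  a2 <- config$rsnp_alleles[2]
  b <- config$assay_bias_b
  conc <- config$noise_concentration
  nrep <- config$n_replicates

  animals <- tibble::tibble(
    breed = rep(names(config$breeds), times = config$breeds))
  animals$sample_id <- sprintf("%s_%03d", animals$breed,
                               stats::ave(seq_len(nrow(animals)), animals$breed,
                                          FUN = seq_along))
  animals$het <- stats::rbinom(nrow(animals), 1, config$rsnp_het_fraction) == 1
  hom_alt <- stats::rbinom(nrow(animals), 1, 0.5) == 1
  animals$genotype <- ifelse(animals$het, paste(a1, a2, sep = "/"),
                             ifelse(hom_alt, paste(a2, a2, sep = "/"),
                                    paste(a1, a1, sep = "/")))
  hets <- animals[animals$het, , drop = FALSE]
  n_het <- nrow(hets)

  # candidate-SNP haplotypes (hap1 carries reporter allele1)
  diplotypes <- NULL
  cand_fold <- NULL
  if (!is.null(config$candidate_snp)) {
    cs <- config$candidate_snp
    p_causal <- if (is.null(cs$p_causal)) 0.5 else cs$p_causal
    r <- sqrt(cs$ld_r2)
    # "high" causal state per haplotype; candidate allele copies it with
    # probability (1 + r) / 2 so cor(candidate, causal) = r at freq 0.5
    high1 <- stats::rbinom(n_het, 1, p_causal) == 1
    high2 <- stats::rbinom(n_het, 1, p_causal) == 1
    agree1 <- stats::rbinom(n_het, 1, (1 + r) / 2) == 1
    agree2 <- stats::rbinom(n_het, 1, (1 + r) / 2) == 1
    cand_ref1 <- ifelse(agree1, high1, !high1)  # ref allele = high-expressing
    cand_ref2 <- ifelse(agree2, high2, !high2)
    cand_fold <- cs$causal_fold^(as.numeric(high1) - as.numeric(high2))
    genot <- ifelse(cand_ref1 & cand_ref2, "hom_ref",
                    ifelse(!cand_ref1 & !cand_ref2, "hom_alt", "het"))
    phase <- ifelse(genot != "het", "unknown",
                    ifelse(cand_ref1, "cis_ref", "cis_alt"))
    diplotypes <- tibble::tibble(
      sample_id = hets$sample_id, breed = hets$breed, gene = gene,
      candidate_snp_id = if (is.null(cs$snp_id)) "candidate" else cs$snp_id,
      candidate_genotype = genot, phase = phase)
  }

  # per-animal x tissue cis fold (constant across tissues when candidate-driven)
  n_tis <- length(config$tissues)
  if (!is.null(cand_fold)) {
    fold <- matrix(rep(cand_fold, n_tis), nrow = n_het)
  } else {
    fold <- matrix(.draw_fold(n_het * n_tis, config$cis_fold_distribution),
                   nrow = n_het)
  }

  export_pct <- function(frac) {
    p1 <- round(100 * frac, 1)
    list(p1 = p1, p2 = 100 - p1)
  }
  meas <- list()
  # gDNA: expected allele1 fraction b / (1 + b)
  for (rep_i in seq_len(nrep)) {
    fr <- .draw_fraction(n_het, b / (1 + b), conc)
    p <- export_pct(fr)
    meas[[length(meas) + 1]] <- tibble::tibble(
      sample_id = hets$sample_id, breed = hets$breed, tissue = "blood",
      gene = gene, material = "gDNA", allele1 = a1, allele2 = a2,
      pct_allele1 = p$p1, pct_allele2 = p$p2, replicate = rep_i)
  }
  # cDNA per tissue: expected allele1 fraction b f / (1 + b f)
  for (ti in seq_len(n_tis)) {
    ef <- b * fold[, ti] / (1 + b * fold[, ti])
    for (rep_i in seq_len(nrep)) {
      fr <- .draw_fraction(n_het, ef, conc)
      p <- export_pct(fr)
      meas[[length(meas) + 1]] <- tibble::tibble(
        sample_id = hets$sample_id, breed = hets$breed,
        tissue = config$tissues[ti], gene = gene, material = "cDNA",
        allele1 = a1, allele2 = a2,
        pct_allele1 = p$p1, pct_allele2 = p$p2, replicate = rep_i)
    }
  }
  measurements <- dplyr::arrange(dplyr::bind_rows(meas),
                                 .data$material, .data$tissue,
                                 .data$sample_id, .data$replicate)

  truth_tissue <- tibble::tibble(
    sample_id = rep(hets$sample_id, times = n_tis),
    tissue = rep(config$tissues, each = n_het),
    true_fold = as.vector(fold),
    over_allele = ifelse(as.vector(fold) > 1, a1,
                         ifelse(as.vector(fold) < 1, a2, NA_character_)),
    ase_true = as.vector(fold) > 1.5 | as.vector(fold) < 1 / 1.5)

  # methylation keyed on true ASE status per tissue
  methylation <- NULL
  if (!is.null(config$methylation)) {
    mrec <- list()
    for (tis in intersect(config$methylation_tissues, config$tissues)) {
      ti <- match(tis, config$tissues)
      is_ase <- fold[, ti] > 1.5 | fold[, ti] < 1 / 1.5
      for (isl in config$methylation) {
        sites <- isl$island$site_positions
        for (si in seq_along(sites)) {
          mu <- ifelse(is_ase, isl$mean_ase[si], isl$mean_ctrl[si])
          val <- pmin(100, pmax(0, stats::rnorm(n_het, mu, isl$sd)))
          mrec[[length(mrec) + 1]] <- tibble::tibble(
            sample_id = hets$sample_id, tissue = tis,
            island_id = isl$island$island_id, chrom = isl$island$chrom,
            position = sites[si], pct_5mc = round(val, 2),
            conversion_control_pass = TRUE)
        }
      }
    }
    methylation <- dplyr::bind_rows(mrec)
  }

  genotypes <- tibble::tibble(
    sample_id = animals$sample_id, breed = animals$breed,
    gene = gene, snp_id = "rsnp", genotype = animals$genotype)

  truth <- list(
    assay = list(gene = gene, bias_b = b,
                 noise_concentration = conc, n_replicates = nrep),
    animals = tibble::tibble(sample_id = animals$sample_id,
                             breed = animals$breed, rsnp_het = animals$het),
    per_tissue = truth_tissue,
    candidate = if (!is.null(diplotypes)) {
      dplyr::mutate(diplotypes, true_fold = cand_fold)
    } else NULL,
    methylation = config$methylation)

  list(measurements = measurements, genotypes = genotypes,
       diplotypes = diplotypes, methylation = methylation, truth = truth)
}

#' Simulate a grid of null/power scenarios with a deterministic manifest
#'
#' Each grid cell fixes an effect size (cis fold), a heterozygote count and
#' a noise level; per-replicate seeds are derived deterministically from the
#' base seed so the whole grid is reproducible from one integer.
#'
#' @param grid Tibble/data.frame with columns `cell_id` (unique), `fold`,
#'   `n_het`, `noise_concentration`, `n_datasets`.
#' @param base_seed Integer; replicate seed is
#'   `base_seed + 10000 * cell_index + replicate`.
#' @param out_dir Optional directory: when given, each dataset's measurement
#'   table is written as `<cell_id>_<replicate>.tsv` and the manifest as
#'   `manifest.json`.
#' @param ... Further arguments passed to [sim_config()] (e.g.
#'   `methylation = NULL`, `tissues`).
#' @return Tibble manifest: one row per dataset with `cell_id`, parameters,
#'   `replicate`, `seed` and (when written) `path`.
#' @export
simulate_null_and_power_grid <- function(grid, base_seed, out_dir = NULL, ...) {
  grid <- tibble::as_tibble(grid)
  stopifnot(all(c("cell_id", "fold", "n_het", "noise_concentration",
                  "n_datasets") %in% names(grid)))
  if (anyDuplicated(grid$cell_id)) {
    rlang::abort("duplicate cell ids in grid", class = "pyroase_manifest_error")
  }
  rows <- list()
  for (ci in seq_len(nrow(grid))) {
    cell <- grid[ci, ]
    for (rep_i in seq_len(cell$n_datasets)) {
      seed <- as.integer(base_seed + 10000L * ci + rep_i)
      rows[[length(rows) + 1]] <- tibble::tibble(
        cell_id = cell$cell_id, fold = cell$fold, n_het = cell$n_het,
        noise_concentration = cell$noise_concentration,
        replicate = rep_i, seed = seed,
        path = if (is.null(out_dir)) NA_character_ else
          file.path(out_dir, sprintf("%s_%03d.tsv", cell$cell_id, rep_i)))
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      cfg <- manifest_config(manifest[i, ], ...)
      sim <- simulate_cohort(cfg)
      utils::write.table(sim$measurements, manifest$path[i], sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", na = "null", auto_unbox = TRUE,
                         digits = NA)
  }
  manifest
}

#' Simulation config for one manifest row
#'
#' @param row One row of a manifest from [simulate_null_and_power_grid()].
#' @param tissues Tissues to simulate (single fat tissue by default for
#'   Monte-Carlo speed).
#' @param ... Further [sim_config()] overrides.
#' @return A [sim_config()] with a point-mass fold at the row's effect, all
#'   animals heterozygous (so group size equals `n_het`), one breed.
#' @export
manifest_config <- function(row, tissues = "visceral_fat", ...) {
  sim_config(seed = row$seed,
             breeds = c(SIM = as.integer(row$n_het)),
             tissues = tissues,
             rsnp_het_fraction = 1,
             cis_fold_distribution = list(type = "point", fold = row$fold),
             noise_concentration = row$noise_concentration,
             methylation = NULL, ...)
}
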