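# End-to-end orchestration: one call runs quantification, classification,
# directionality, the breed x tissue summary, candidate-variant association
# and methylation comparison, writing every output table plus an exclusion
# log and a run log of counts at each filter.

#' Build a validated pipeline configuration
#'
#' @param lower,upper ASE classification thresholds (`0 < lower < 1 <
#'   upper`); defaults 2/3 (printed 0.667) and 1.5 — the 60:40 rule with
#'   exactly reciprocal bounds.
#' @param min_het Minimum reporter-SNP heterozygotes for a gene x breed
#'   group to be analysed (default 10).
#' @param control_band Half-width of the balanced-control ratio band around
#'   1 for the methylation comparison (default 0.15).
#' @param control_n Cap on the control group size (default 10, matching the
#'   study's control groups).
#' @param neutralize Neutralize ratios before log10 in group tests (used for
#'   genes with bi-directional ASE).
#' @param per_breed_bias Estimate gDNA bias per gene x breed instead of
#'   pooled per gene.
#' @param pool_gdna Pool gDNA across breeds in the summary table.
#' @param methylation_welch Use Welch instead of the pooled Student t for
#'   per-CpG comparisons.
#' @param bh_correct Add Benjamini-Hochberg adjusted p-values to test
#'   outputs (raw p is always reported).
#' @param average Replicate-averaging order, see [average_replicates()].
#' @param islands List of [cpg_island()] objects for the methylation stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(lower = 2 / 3, upper = 1.5, min_het = 10,
                            control_band = 0.15, control_n = 10,
                            neutralize = TRUE, per_breed_bias = FALSE,
                            pool_gdna = FALSE, methylation_welch = FALSE,
                            bh_correct = FALSE,
                            average = "ratio_first",
                            islands = NULL) {
  if (!(lower > 0 && lower < 1 && upper > 1)) {
    rlang::abort("thresholds must satisfy 0 < lower < 1 < upper",
                 class = "pyroase_config_error")
  }
  if (min_het < 1 || control_band <= 0) {
    rlang::abort("min_het must be >= 1 and control_band > 0",
                 class = "pyroase_config_error")
  }
  structure(list(lower = lower, upper = upper, min_het = min_het,
                 control_band = control_band, control_n = control_n,
                 neutralize = neutralize, per_breed_bias = per_breed_bias,
                 pool_gdna = pool_gdna, methylation_welch = methylation_welch,
                 bh_correct = bh_correct, average = average,
                 islands = islands),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; an
#' `islands` block (list of `island_id`, `chrom`, `start`, `end`,
#' `site_positions`) is converted to [cpg_island()] objects.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  islands <- NULL
  if (!is.null(y$islands)) {
    islands <- lapply(y$islands, function(isl) {
      cpg_island(isl$island_id, isl$chrom, isl$start, isl$end,
                 unlist(isl$site_positions))
    })
    y$islands <- NULL
  }
  do.call(pipeline_config, c(y, list(islands = islands)))
}

#' Run the full ASE pipeline
#'
#' Stages, in order: measurement validation; the >= `min_het` heterozygote
#' rule per gene x breed; gDNA bias estimation and ratio normalization;
#' replicate averaging; 60:40 classification; directionality;
#' breed x tissue summary with Welch tests against gDNA; candidate-variant
#' association on phase-corrected ratios (when diplotypes are supplied);
#' per-CpG methylation comparison between ASE and balanced-control groups
#' (when methylation records and island configs are supplied). Every record
#' removed by a filter lands in the exclusion log with a reason code; a
#' plain-text run log records counts at each stage (no timestamps, so
#' repeated runs on identical inputs are byte-identical).
#'
#' @param measurements Replicate-level measurement tibble, or a TSV path.
#' @param genotypes Reporter-SNP genotype tibble (or TSV path) covering all
#'   genotyped animals.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @param diplotypes Optional candidate-variant tibble: `sample_id`,
#'   `gene`, `candidate_genotype`, `phase` (see [test_variant_association()]).
#' @param methylation Optional per-CpG methylation tibble (or TSV path).
#' @return Invisibly, a list: `ratios`, `ase_calls`, `directionality`,
#'   `summary` (per gene), `variant_tests`, `methylation_tests`,
#'   `exclusions`, `informative`, `log` (character lines).
#' @export
run_pipeline <- function(measurements, genotypes, config = pipeline_config(),
                         out_dir = NULL, diplotypes = NULL, methylation = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(measurements)) {
    parts <- read_pyro_tsv(measurements)
  } else {
    parts <- validate_measurements(measurements)
  }
  if (is.character(genotypes)) genotypes <- read_genotypes_tsv(genotypes)
  if (is.character(methylation)) methylation <- read_methylation_tsv(methylation)

  exclusions <- list()
  if (nrow(parts$excluded) > 0) {
    exclusions[[length(exclusions) + 1]] <- tibble::tibble(
      record_type = "measurement",
      id = sprintf("%s:%s:%s:rep%s", parts$excluded$sample_id,
                   parts$excluded$gene, parts$excluded$material,
                   parts$excluded$replicate),
      reason = parts$excluded$reason)
  }
  m <- parts$valid
  log_lines <- c(
    sprintf("measurements: %d rows read, %d valid, %d excluded",
            nrow(parts$valid) + nrow(parts$excluded), nrow(parts$valid),
            nrow(parts$excluded)),
    sprintf("genotyped animals: %d", length(unique(genotypes$sample_id))))

  # heterozygote filter: keep het animals in informative gene x breed groups
  informative <- filter_informative_groups(genotypes, min_het = config$min_het)
  gkey <- if ("gene" %in% names(informative)) "gene" else "snp_id"
  het_animals <- genotypes[which(is_heterozygous(genotypes$genotype)), , drop = FALSE]
  log_lines <- c(log_lines,
                 sprintf("heterozygous animals: %d", length(unique(het_animals$sample_id))),
                 sprintf("informative gene x breed groups (>= %d hets): %d of %d",
                         config$min_het, sum(informative$retained), nrow(informative)))
  dropped_groups <- informative[!informative$retained, , drop = FALSE]
  if (nrow(dropped_groups) > 0) {
    exclusions[[length(exclusions) + 1]] <- tibble::tibble(
      record_type = "group",
      id = sprintf("%s:%s", dropped_groups[[gkey]], dropped_groups$breed),
      reason = sprintf("fewer_than_%d_heterozygotes(n=%d)",
                       config$min_het, dropped_groups$n_het))
  }
  keep_groups <- informative[informative$retained, , drop = FALSE]
  gene_col <- if ("gene" %in% names(m)) "gene" else gkey
  m_in <- dplyr::semi_join(
    m, dplyr::rename(keep_groups, !!gene_col := !!gkey), by = c(gene_col, "breed"))
  m_in <- dplyr::semi_join(m_in, het_animals, by = "sample_id")
  n_drop <- nrow(m) - nrow(m_in)
  if (n_drop > 0) {
    dropped <- dplyr::anti_join(m, m_in,
                                by = c("sample_id", gene_col, "material",
                                       "tissue", "replicate"))
    exclusions[[length(exclusions) + 1]] <- tibble::tibble(
      record_type = "measurement",
      id = sprintf("%s:%s:%s:rep%s", dropped$sample_id, dropped[[gene_col]],
                   dropped$material, dropped$replicate),
      reason = "uninformative_group_or_not_heterozygous")
  }
  log_lines <- c(log_lines,
                 sprintf("measurements after heterozygote/group filters: %d", nrow(m_in)))

  ratios <- allelic_ratio_table(m_in, per_breed_bias = config$per_breed_bias,
                                average = config$average)
  ase_calls <- classify_ase(ratios, lower = config$lower, upper = config$upper)
  log_lines <- c(log_lines,
                 sprintf("ratio rows: %d (cDNA %d, gDNA %d); ASE calls: %d",
                         nrow(ratios), sum(ratios$material == "cDNA"),
                         sum(ratios$material == "gDNA"), nrow(ase_calls)))

  directionality <- ase_calls |>
    dplyr::group_by(.data$gene, .data$breed, .data$tissue) |>
    dplyr::group_modify(~ classify_directionality(.x$category)) |>
    dplyr::ungroup()

  summaries <- lapply(split(ratios, ratios$gene), aggregate_summary_table,
                      neutralize_first = config$neutralize,
                      pool_gdna = config$pool_gdna)

  variant_tests <- NULL
  if (!is.null(diplotypes)) {
    cd <- ratios[ratios$material == "cDNA", , drop = FALSE]
    by_cols <- intersect(c("sample_id", "gene"), names(diplotypes))
    joined <- dplyr::inner_join(cd, diplotypes, by = by_cols)
    variant_tests <- joined |>
      dplyr::group_by(.data$gene, .data$tissue, .data$candidate_snp_id) |>
      dplyr::group_modify(function(d, key) {
        res <- tryCatch(test_variant_association(d),
                        pyroase_insufficient_sample = function(e) NULL,
                        pyroase_degenerate_variance = function(e) NULL)
        if (is.null(res)) tibble::tibble() else res
      }) |>
      dplyr::ungroup()
    if (config$bh_correct && nrow(variant_tests) > 0) {
      variant_tests$p_adjusted <- stats::p.adjust(variant_tests$p_value, "BH")
    }
  }

  methylation_tests <- NULL
  if (!is.null(methylation) && !is.null(config$islands)) {
    if ("conversion_control_pass" %in% names(methylation)) {
      failed <- !methylation$conversion_control_pass
      if (any(failed)) {
        exclusions[[length(exclusions) + 1]] <- tibble::tibble(
          record_type = "methylation",
          id = sprintf("%s:%s:%d", methylation$sample_id[failed],
                       methylation$island_id[failed],
                       methylation$position[failed]),
          reason = "conversion_control_failed")
        methylation <- methylation[!failed, , drop = FALSE]
      }
    }
    mt <- list()
    for (isl in config$islands) {
      for (tis in unique(methylation$tissue[methylation$island_id == isl$island_id])) {
        recs <- methylation[methylation$island_id == isl$island_id &
                              methylation$tissue == tis, , drop = FALSE]
        calls_t <- ase_calls[ase_calls$tissue == tis, , drop = FALSE]
        ase_ids <- calls_t$sample_id[calls_t$category != "balanced"]
        ctrl_ids <- select_control_group(calls_t, ratios[ratios$tissue == tis, ],
                                         band = config$control_band,
                                         n_max = config$control_n)
        ctrl_ids <- setdiff(ctrl_ids, ase_ids)
        a_rec <- recs[recs$sample_id %in% ase_ids, , drop = FALSE]
        c_rec <- recs[recs$sample_id %in% ctrl_ids, , drop = FALSE]
        if (nrow(a_rec) == 0 || nrow(c_rec) == 0) next
        cmp <- compare_methylation(a_rec, c_rec, isl,
                                   welch = config$methylation_welch)
        cmp$tissue <- tis
        mt[[length(mt) + 1]] <- cmp
      }
    }
    methylation_tests <- dplyr::bind_rows(mt)
    if (config$bh_correct && !is.null(methylation_tests) &&
        nrow(methylation_tests) > 0) {
      methylation_tests$p_adjusted <- stats::p.adjust(methylation_tests$p_value, "BH")
    }
  }

  exclusions <- if (length(exclusions) > 0) dplyr::bind_rows(exclusions) else
    tibble::tibble(record_type = character(), id = character(),
                   reason = character())
  log_lines <- c(log_lines, sprintf("exclusion log entries: %d", nrow(exclusions)))

  result <- list(ratios = ratios, ase_calls = ase_calls,
                 directionality = directionality, summary = summaries,
                 variant_tests = variant_tests,
                 methylation_tests = methylation_tests,
                 exclusions = exclusions, informative = informative,
                 log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pyro_tsv(ratios, file.path(out_dir, "normalized_ratios.tsv"))
    write_pyro_tsv(ase_calls, file.path(out_dir, "ase_calls.tsv"))
    write_pyro_tsv(directionality, file.path(out_dir, "directionality.tsv"))
    for (g in names(summaries)) {
      write_pyro_tsv(summaries[[g]]$table,
                     file.path(out_dir, sprintf("summary_%s.tsv", g)))
      write_pyro_tsv(summaries[[g]]$cells,
                     file.path(out_dir, sprintf("summary_cells_%s.tsv", g)))
      write_pyro_tsv(summaries[[g]]$five_number,
                     file.path(out_dir, sprintf("five_number_%s.tsv", g)))
    }
    all_tests <- dplyr::bind_rows(lapply(summaries, function(s) s$tests))
    if (!is.null(variant_tests) && nrow(variant_tests) > 0) {
      write_pyro_tsv(variant_tests, file.path(out_dir, "variant_association.tsv"))
      all_tests <- dplyr::bind_rows(all_tests, variant_tests)
    }
    jsonlite::write_json(all_tests, file.path(out_dir, "group_tests.json"),
                         dataframe = "rows", na = "null", auto_unbox = TRUE,
                         digits = NA)
    if (!is.null(methylation_tests) && nrow(methylation_tests) > 0) {
      write_pyro_tsv(methylation_tests,
                     file.path(out_dir, "methylation_comparison.tsv"))
    }
    write_pyro_tsv(exclusions, file.path(out_dir, "exclusions.tsv"))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(result)
}
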