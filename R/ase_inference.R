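# Group-level inference: Welch comparison of cDNA vs gDNA log10 ratios,
# directionality, the >=10-heterozygote informativeness rule, phase-corrected
# promoter-variant association, and the Table-1-style summary.

#' Significance code for a p-value
#'
#' Strict thresholds, most stringent applicable: `***` for p < 0.001, `**`
#' for p < 0.01, `*` for p < 0.05, otherwise `ns`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of codes.
#' @export
significance_code <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns")
}

#' Two-tailed Welch t-test between two groups
#'
#' Unequal-variance (Welch) two-sample t-test with the Welch-Satterthwaite
#' approximation for the degrees of freedom, as used throughout for
#' cDNA-vs-gDNA and genotype-group comparisons of log10 allelic transcript
#' ratios. Groups in which both variances are exactly zero are rejected
#' rather than returning an undefined statistic.
#'
#' @param xs,ys Numeric vectors, each with at least 2 finite values.
#' @param group1_label,group2_label Labels recorded in the result.
#' @return One-row tibble: `group1_label`, `group2_label`, `n1`, `n2`,
#'   `mean1`, `mean2`, `t_statistic`, `df`, `p_value`, `significance_code`.
#' @export
welch_t_test <- function(xs, ys, group1_label = "group1", group2_label = "group2") {
  if (length(xs) < 2 || length(ys) < 2) {
    rlang::abort("each group needs at least 2 observations",
                 class = "pyroase_insufficient_sample")
  }
  if (any(!is.finite(xs)) || any(!is.finite(ys))) {
    rlang::abort("groups must contain only finite values",
                 class = "pyroase_insufficient_sample")
  }
  if (stats::var(xs) == 0 && stats::var(ys) == 0) {
    if (isTRUE(all.equal(mean(xs), mean(ys)))) {
      # identical constant groups: no evidence of difference
      return(tibble::tibble(
        group1_label = group1_label, group2_label = group2_label,
        n1 = length(xs), n2 = length(ys),
        mean1 = mean(xs), mean2 = mean(ys),
        t_statistic = 0, df = length(xs) + length(ys) - 2,
        p_value = 1, significance_code = "ns"))
    }
    rlang::abort("both groups have zero variance: t statistic undefined",
                 class = "pyroase_degenerate_variance")
  }
  ht <- stats::t.test(xs, ys, var.equal = FALSE, alternative = "two.sided")
  tibble::tibble(
    group1_label = group1_label, group2_label = group2_label,
    n1 = length(xs), n2 = length(ys),
    mean1 = mean(xs), mean2 = mean(ys),
    t_statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    significance_code = significance_code(ht$p.value))
}

#' Test cDNA-vs-gDNA deviation of mean allelic expression
#'
#' Compares log10-transformed allelic transcript ratios of cDNA samples (one
#' breed x tissue) against heterozygous gDNA samples with a two-tailed Welch
#' t-test. With `neutralize_first = TRUE` (used for genes with bi-directional
#' ASE) both groups' ratios pass through [neutralize()] before the log
#' transform, so the comparison is on imbalance magnitude.
#'
#' @param cdna_ratios,gdna_ratios Positive numeric vectors of normalized
#'   allelic ratios (not yet logged).
#' @param neutralize_first Neutralize both groups before log10.
#' @param group1_label,group2_label Labels recorded in the result.
#' @return One-row tibble as from [welch_t_test()].
#' @export
test_cdna_vs_gdna <- function(cdna_ratios, gdna_ratios, neutralize_first = TRUE,
                              group1_label = "cDNA", group2_label = "gDNA") {
  if (neutralize_first) {
    cdna_ratios <- neutralize(cdna_ratios)
    gdna_ratios <- neutralize(gdna_ratios)
  }
  welch_t_test(log10(cdna_ratios), log10(gdna_ratios),
               group1_label = group1_label, group2_label = group2_label)
}

#' Directionality of ASE within one gene x breed x tissue group
#'
#' One-directional ASE (the same allele over-represented in all imbalanced
#' heterozygotes) points to a cis element in linkage disequilibrium with the
#' gene; bi-directional ASE (either allele over-expressed in different
#' animals) points to an unlinked regulatory variant.
#'
#' @param calls ASE-call tibble (from [classify_ase()]) for one group, or a
#'   factor/character vector of categories.
#' @return One-row tibble with `value` in `none` / `one_directional` /
#'   `bi_directional` and the per-direction counts.
#' @export
classify_directionality <- function(calls) {
  categories <- if (is.data.frame(calls)) calls$category else calls
  if (length(categories) == 0) {
    rlang::abort("no ASE calls in group", class = "pyroase_empty_group")
  }
  n1 <- sum(categories == "ase_allele1")
  n2 <- sum(categories == "ase_allele2")
  value <- if (n1 > 0 && n2 > 0) "bi_directional"
           else if (n1 > 0 || n2 > 0) "one_directional"
           else "none"
  out <- tibble::tibble(value = value, n_ase_allele1 = n1, n_ase_allele2 = n2)
  if (is.data.frame(calls)) {
    keep <- intersect(c("gene", "breed", "tissue"), names(calls))
    for (col in rev(keep)) out <- dplyr::bind_cols(calls[1, col], out)
  }
  out
}

#' Informative gene x breed groups under the heterozygote rule
#'
#' Quantitative ASE analysis is restricted to breeds with at least `min_het`
#' heterozygotes for the gene's reporter SNP; all other groups are flagged
#' excluded with their heterozygote count.
#'
#' @param genotypes Tibble with columns `sample_id`, `breed`, `gene` (or
#'   `snp_id`), and `genotype` written as `"A/T"`-style strings.
#' @param min_het Minimum heterozygote count (default 10).
#' @return Tibble with one row per gene x breed: `n_het`, `retained`.
#' @export
filter_informative_groups <- function(genotypes, min_het = 10) {
  key <- if ("gene" %in% names(genotypes)) "gene" else "snp_id"
  if (nrow(genotypes) == 0) {
    return(tibble::tibble(!!key := character(), breed = character(),
                          n_het = integer(), retained = logical()))
  }
  genotypes |>
    dplyr::mutate(.het = is_heterozygous(.data$genotype)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(key, "breed")))) |>
    dplyr::summarise(n_het = sum(.data$.het, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(retained = .data$n_het >= min_het)
}

#' @rdname filter_informative_groups
#' @param genotype Character vector like `"A/T"`, `"A|T"` or `"AT"`; `"."`
#'   or `NA` is missing.
#' @return For `is_heterozygous`: logical vector (`NA` for missing).
#' @export
is_heterozygous <- function(genotype) {
  g <- gsub("[/|]", "", genotype)
  out <- nchar(g) == 2 & substr(g, 1, 1) != substr(g, 2, 2)
  out[is.na(genotype) | genotype == "."] <- NA
  out
}

#' Phase-correct a log10 allelic ratio for a candidate-variant heterozygote
#'
#' Re-orients each reporter-SNP heterozygote's log ratio so the numerator
#' haplotype always carries the candidate variant's reference allele: when
#' the candidate's alternate allele lies on the same haplotype as the
#' reporter's numerator allele (`phase = "cis_alt"`) the sign is flipped;
#' `"cis_ref"` leaves it unchanged. Candidate homozygotes pass through
#' unchanged (phase is irrelevant). Flipping the sign is equivalent to
#' taking the reciprocal of the ratio before the log transform.
#'
#' @param log10_ratio Numeric vector of log10 normalized allelic ratios.
#' @param candidate_genotype Character vector in `hom_ref` / `het` /
#'   `hom_alt`.
#' @param phase Character vector in `cis_ref` / `cis_alt` / `unknown`;
#'   required (known) wherever `candidate_genotype == "het"`.
#' @return Numeric vector of phase-corrected log10 ratios.
#' @export
phase_correct <- function(log10_ratio, candidate_genotype, phase) {
  stopifnot(all(candidate_genotype %in% c("hom_ref", "het", "hom_alt")))
  het <- candidate_genotype == "het"
  if (any(het & (is.na(phase) | !phase %in% c("cis_ref", "cis_alt")))) {
    rlang::abort("candidate heterozygote with unknown phase cannot be corrected",
                 class = "pyroase_unphased_record")
  }
  flip <- het & phase == "cis_alt"
  ifelse(flip, -log10_ratio, log10_ratio)
}

#' Candidate-variant association via phase-corrected ratios
#'
#' Tests whether a candidate (promoter) variant shifts allelic expression by
#' comparing phase-corrected log10 allelic transcript ratios of
#' candidate-SNP heterozygotes against the (uncorrected) log ratios of
#' candidate homozygotes, all within reporter-SNP heterozygotes. Because
#' every comparison is within-sample, trans and environmental confounders
#' cancel. Two-tailed Welch t-test.
#'
#' @param diplotypes Tibble with columns `log10_ratio`, `candidate_genotype`
#'   (`hom_ref`/`het`/`hom_alt`) and `phase` (`cis_ref`/`cis_alt`/`unknown`).
#' @param het_label,hom_label Labels recorded in the result (e.g. the
#'   diplotype groups compared).
#' @return One-row tibble as from [welch_t_test()].
#' @export
test_variant_association <- function(diplotypes,
                                     het_label = "candidate_het",
                                     hom_label = "candidate_hom") {
  stopifnot(all(c("log10_ratio", "candidate_genotype", "phase") %in% names(diplotypes)))
  het <- diplotypes$candidate_genotype == "het"
  if (!any(het) || !any(!het)) {
    rlang::abort("need both candidate heterozygotes and homozygotes",
                 class = "pyroase_insufficient_sample")
  }
  xs <- phase_correct(diplotypes$log10_ratio[het],
                      diplotypes$candidate_genotype[het],
                      diplotypes$phase[het])
  ys <- diplotypes$log10_ratio[!het]
  welch_t_test(xs, ys, group1_label = het_label, group2_label = hom_label)
}

#' Breed x tissue summary of mean log10 allelic transcript ratios
#'
#' Builds the aggregate summary: one row per breed, one column per tissue
#' plus a gDNA column, each cell the mean log10 (optionally neutralized)
#' normalized ratio, with a significance code from the Welch comparison of
#' that breed x tissue's cDNA ratios against the breed's gDNA ratios. Also
#' returns per-group five-number summaries (min, Q1, median, Q3, max) of the
#' normalized ratios, and the full test records.
#'
#' @param ratios Tibble from [allelic_ratio_table()] for one gene, with
#'   `breed`, `tissue`, `material`, `normalized_ratio`.
#' @param neutralize_first Neutralize ratios before log10 (used for genes
#'   with bi-directional ASE).
#' @param pool_gdna Pool gDNA across breeds for the comparison column
#'   (default `FALSE`: each breed row is anchored on its own gDNA).
#' @return List with `table` (wide, cell strings `"mean code"`), `cells`
#'   (long: mean, n, p, code per breed x tissue), `tests` (all Welch
#'   results) and `five_number` (per-group ratio quantiles).
#' @export
aggregate_summary_table <- function(ratios, neutralize_first = TRUE,
                                    pool_gdna = FALSE) {
  stopifnot(all(c("breed", "tissue", "material", "normalized_ratio") %in% names(ratios)))
  gd <- ratios[ratios$material == "gDNA", , drop = FALSE]
  cd <- ratios[ratios$material == "cDNA", , drop = FALSE]
  if (nrow(gd) == 0) {
    rlang::abort("no gDNA group to anchor the comparison",
                 class = "pyroase_cannot_anchor")
  }
  xform <- function(r) log10(if (neutralize_first) neutralize(r) else r)

  breeds <- sort(unique(cd$breed))
  tissues <- sort(unique(cd$tissue))
  cells <- list()
  tests <- list()
  for (b in breeds) {
    gref <- if (pool_gdna) gd$normalized_ratio else gd$normalized_ratio[gd$breed == b]
    for (ti in tissues) {
      cr <- cd$normalized_ratio[cd$breed == b & cd$tissue == ti]
      if (length(cr) == 0) next
      res <- test_cdna_vs_gdna(cr, gref, neutralize_first = neutralize_first,
                               group1_label = paste(b, ti, sep = ":"),
                               group2_label = paste0(if (pool_gdna) "pooled" else b, ":gDNA"))
      tests[[length(tests) + 1]] <- res
      cells[[length(cells) + 1]] <- tibble::tibble(
        breed = b, tissue = ti, mean_log10 = mean(xform(cr)), n = length(cr),
        p_value = res$p_value, significance_code = res$significance_code)
    }
    cells[[length(cells) + 1]] <- tibble::tibble(
      breed = b, tissue = "gDNA", mean_log10 = mean(xform(gref)),
      n = length(gref), p_value = NA_real_, significance_code = NA_character_)
  }
  cells <- dplyr::bind_rows(cells)
  tests <- dplyr::bind_rows(tests)

  wide <- cells |>
    dplyr::mutate(cell = ifelse(
      is.na(.data$significance_code) | .data$significance_code == "ns",
      sprintf("%.3f", .data$mean_log10),
      sprintf("%.3f %s", .data$mean_log10, .data$significance_code))) |>
    dplyr::select("breed", "tissue", "cell") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "cell")

  five_number <- dplyr::bind_rows(cd, gd) |>
    dplyr::mutate(group = ifelse(.data$material == "gDNA", "gDNA", .data$tissue)) |>
    dplyr::group_by(.data$breed, .data$group) |>
    dplyr::summarise(
      min = min(.data$normalized_ratio),
      q1 = unname(stats::quantile(.data$normalized_ratio, 0.25)),
      median = stats::median(.data$normalized_ratio),
      q3 = unname(stats::quantile(.data$normalized_ratio, 0.75)),
      max = max(.data$normalized_ratio),
      n = dplyr::n(), .groups = "drop")

  list(table = wide, cells = cells, tests = tests, five_number = five_number)
}
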