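# Ratio arithmetic for pyrosequencing allele percentages: raw ratios,
# gDNA incorporation-bias normalization, replicate averaging, neutralization
# and 60:40 threshold classification.

#' Allelic transcript ratio from allele percentages
#'
#' The allelic transcript ratio is the percentage of the assay's first
#' (numerator) allele divided by the percentage of the second. A 60:40
#' allelic proportion therefore corresponds to a ratio of 1.5 and 40:60 to
#' 0.667. Percentages of exactly 0 or 100 indicate a failed assay or a
#' genotyping error (a true heterozygote cannot express 0% of one allele at
#' pyrosequencing depth) and are rejected rather than clamped.
#'
#' @param pct_allele1,pct_allele2 Numeric vectors of allele percentages in
#'   (0, 100]. Each pair must sum to 100 within `sum_tol`.
#' @param sum_tol Tolerance on the pairwise sum (default 0.5, allowing for
#'   rounding in instrument exports).
#' @return Numeric vector `pct_allele1 / pct_allele2` (always positive).
#' @examples
#' compute_ratio(60, 40) # 1.5
#' compute_ratio(40, 60) # 0.667
#' @export
compute_ratio <- function(pct_allele1, pct_allele2, sum_tol = 0.5) {
  if (length(pct_allele1) != length(pct_allele2)) {
    rlang::abort("allele percentage vectors must have equal length",
                 class = "pyroase_invalid_measurement")
  }
  bad <- !is.finite(pct_allele1) | !is.finite(pct_allele2) |
    pct_allele1 <= 0 | pct_allele2 <= 0 |
    pct_allele1 > 100 | pct_allele2 > 100
  if (any(bad)) {
    rlang::abort(
      sprintf("invalid allele percentages (zero, negative, > 100 or missing) in %d measurement(s): failed pyrosequencing assay",
              sum(bad)),
      class = "pyroase_invalid_measurement")
  }
  off <- abs(pct_allele1 + pct_allele2 - 100) > sum_tol
  if (any(off)) {
    rlang::abort(
      sprintf("allele percentages do not sum to 100 +/- %g in %d measurement(s)",
              sum_tol, sum(off)),
      class = "pyroase_invalid_measurement")
  }
  pct_allele1 / pct_allele2
}

#' Estimate per-assay incorporation bias from heterozygous gDNA
#'
#' In genomic DNA of a heterozygote an equimolar allele ratio is expected, so
#' any systematic deviation of the mean gDNA allelic ratio from 1 measures
#' the assay's nucleotide-incorporation bias. The estimate is the arithmetic
#' mean of raw gDNA ratios for the assay; it is later divided out of every
#' cDNA and gDNA ratio.
#'
#' @param gdna_ratios Positive numeric vector of raw allelic ratios measured
#'   in heterozygous gDNA for one gene/assay.
#' @return The assay bias (positive scalar).
#' @export
estimate_gdna_bias <- function(gdna_ratios) {
  if (length(gdna_ratios) == 0) {
    rlang::abort("no heterozygous gDNA control ratios: cannot estimate assay bias",
                 class = "pyroase_insufficient_control")
  }
  if (any(!is.finite(gdna_ratios) | gdna_ratios <= 0)) {
    rlang::abort("gDNA control ratios must be positive and finite",
                 class = "pyroase_invalid_measurement")
  }
  mean(gdna_ratios)
}

#' Normalize a raw allelic ratio by the assay's gDNA bias
#'
#' @param raw_ratio Positive numeric vector of raw ratios.
#' @param gdna_bias Positive scalar (or vector recycled against `raw_ratio`)
#'   from [estimate_gdna_bias()].
#' @return `raw_ratio / gdna_bias`.
#' @export
normalize_ratio <- function(raw_ratio, gdna_bias) {
  if (any(!is.finite(gdna_bias) | gdna_bias <= 0)) {
    rlang::abort("gDNA bias must be positive and finite",
                 class = "pyroase_invalid_assay")
  }
  if (any(!is.finite(raw_ratio) | raw_ratio <= 0)) {
    rlang::abort("raw ratios must be positive and finite",
                 class = "pyroase_invalid_measurement")
  }
  raw_ratio / gdna_bias
}

#' Neutralize the direction of an allelic ratio
#'
#' Maps a ratio r to max(r, 1/r) so the magnitude of imbalance can be
#' averaged regardless of which allele is over-expressed (bi-directional
#' ASE). The result is always >= 1 and its log10 is |log10(r)|.
#'
#' @param ratio Positive numeric vector.
#' @return Numeric vector of neutralized ratios, all >= 1.
#' @export
neutralize <- function(ratio) {
  if (any(!is.finite(ratio) | ratio <= 0)) {
    rlang::abort("ratios must be positive and finite", class = "pyroase_domain_error")
  }
  pmax(ratio, 1 / ratio)
}

#' Average replicate measurements into per-sample allelic ratios
#'
#' Each replicate's raw ratio is normalized by the assay's gDNA bias first,
#' then the normalized ratios are arithmetically averaged; `replicate_sd` is
#' the sample standard deviation of the per-replicate normalized ratios (0
#' for a single replicate). Averaging percentages before ratio-ing is
#' available as a configuration alternative via `average = "percent_first"`.
#'
#' @param measurements Tibble of replicate measurements for one
#'   sample/gene/material with columns `pct_allele1`, `pct_allele2` and
#'   identifying columns `sample_id`, `gene`, `material` (plus optional
#'   `breed`, `tissue`, `allele1`, `allele2`).
#' @param gdna_bias Positive scalar assay bias.
#' @param average Either `"ratio_first"` (default: normalize each replicate's
#'   ratio, then average) or `"percent_first"` (average percentages across
#'   replicates, then form and normalize a single ratio).
#' @return One-row tibble with `raw_ratio` (mean of per-replicate raw
#'   ratios), `normalized_ratio`, `n_replicates`, `replicate_sd`,
#'   `neutralized_ratio` and `log10_ratio` (log10 of the normalized ratio).
#' @export
average_replicates <- function(measurements, gdna_bias,
                               average = c("ratio_first", "percent_first")) {
  average <- match.arg(average)
  if (nrow(measurements) < 1) {
    rlang::abort("no measurements to average", class = "pyroase_inconsistent_group")
  }
  key_cols <- intersect(c("sample_id", "gene", "material", "allele1", "allele2"),
                        names(measurements))
  for (col in key_cols) {
    if (length(unique(measurements[[col]])) > 1) {
      rlang::abort(sprintf("replicates mix more than one value of '%s'", col),
                   class = "pyroase_inconsistent_group")
    }
  }
  raw <- compute_ratio(measurements$pct_allele1, measurements$pct_allele2)
  norm <- normalize_ratio(raw, gdna_bias)
  if (average == "ratio_first") {
    mean_norm <- mean(norm)
  } else {
    mean_norm <- normalize_ratio(
      compute_ratio(mean(measurements$pct_allele1), mean(measurements$pct_allele2)),
      gdna_bias)
  }
  out <- measurements[1, setdiff(names(measurements),
                                 c("pct_allele1", "pct_allele2", "replicate")),
                      drop = FALSE]
  dplyr::bind_cols(
    tibble::as_tibble(out),
    tibble::tibble(
      raw_ratio = mean(raw),
      normalized_ratio = mean_norm,
      n_replicates = length(norm),
      replicate_sd = if (length(norm) > 1) stats::sd(norm) else 0,
      neutralized_ratio = neutralize(mean_norm),
      log10_ratio = log10(mean_norm)
    ))
}

#' Per-sample allelic ratio table from replicate-level measurements
#'
#' Pipeline convenience over [estimate_gdna_bias()], [normalize_ratio()] and
#' [average_replicates()]: estimates each gene's incorporation bias from its
#' heterozygous gDNA measurements (pooled across breeds by default),
#' normalizes every replicate ratio by it, and averages replicates within
#' sample x gene x tissue x material.
#'
#' @param measurements Replicate-level tibble with columns `sample_id`,
#'   `breed`, `tissue`, `gene`, `material` ("cDNA"/"gDNA"), `allele1`,
#'   `allele2`, `pct_allele1`, `pct_allele2`, `replicate`.
#' @param gdna_bias Optional named numeric vector of per-gene biases; when
#'   `NULL` (default) biases are estimated from the gDNA rows of
#'   `measurements`.
#' @param per_breed_bias Estimate the bias separately per gene x breed
#'   (default `FALSE`: pooled per gene, one bias per assay).
#' @param average Replicate-averaging order, see [average_replicates()].
#' @return Tibble with one row per sample x gene x tissue x material carrying
#'   the averaged `raw_ratio`, `normalized_ratio`, `n_replicates`,
#'   `replicate_sd`, `neutralized_ratio` and `log10_ratio`.
#' @export
allelic_ratio_table <- function(measurements, gdna_bias = NULL,
                                per_breed_bias = FALSE,
                                average = c("ratio_first", "percent_first")) {
  average <- match.arg(average)
  stopifnot(all(c("sample_id", "gene", "material", "pct_allele1", "pct_allele2")
                %in% names(measurements)))
  measurements <- tibble::as_tibble(measurements)
  measurements$.raw <- compute_ratio(measurements$pct_allele1,
                                     measurements$pct_allele2)

  if (is.null(gdna_bias)) {
    gd <- measurements[measurements$material == "gDNA", , drop = FALSE]
    if (nrow(gd) == 0) {
      rlang::abort("no gDNA control measurements: cannot estimate assay bias",
                   class = "pyroase_insufficient_control")
    }
    bias_keys <- if (per_breed_bias) c("gene", "breed") else "gene"
    bias_tbl <- gd |>
      dplyr::group_by(dplyr::across(dplyr::all_of(bias_keys))) |>
      dplyr::summarise(gdna_bias = estimate_gdna_bias(.data$.raw), .groups = "drop")
  } else {
    bias_tbl <- tibble::tibble(gene = names(gdna_bias), gdna_bias = unname(gdna_bias))
    bias_keys <- "gene"
  }

  joined <- dplyr::inner_join(measurements, bias_tbl, by = bias_keys)
  if (nrow(joined) < nrow(measurements)) {
    rlang::abort("some measurements have no matching assay bias",
                 class = "pyroase_insufficient_control")
  }

  grp_cols <- intersect(c("sample_id", "breed", "tissue", "gene", "material",
                          "allele1", "allele2"), names(joined))
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols)), .data$gdna_bias) |>
    dplyr::summarise(
      raw_ratio = mean(.data$.raw),
      normalized_ratio = if (average == "ratio_first") {
        mean(.data$.raw / .data$gdna_bias[1])
      } else {
        (mean(.data$pct_allele1) / mean(.data$pct_allele2)) / .data$gdna_bias[1]
      },
      n_replicates = dplyr::n(),
      replicate_sd = if (dplyr::n() > 1) stats::sd(.data$.raw / .data$gdna_bias[1]) else 0,
      .groups = "drop") |>
    dplyr::mutate(
      neutralized_ratio = neutralize(.data$normalized_ratio),
      log10_ratio = log10(.data$normalized_ratio))
}

#' Classify allelic ratios against the 60:40 threshold
#'
#' A sample shows ASE toward the numerator allele when its replicate-mean
#' normalized ratio is strictly above `upper` (default 1.5, i.e. > 60:40)
#' and toward the other allele when strictly below `lower` (default 2/3,
#' conventionally printed as 0.667, i.e. < 40:60); values at or between the
#' thresholds are balanced. The default lower threshold is exactly the
#' reciprocal of the upper one so that relabeling the alleles (ratio ->
#' 1/ratio) swaps the two ASE categories and leaves balanced calls fixed.
#'
#' @param ratios Either a numeric vector of ratios or a tibble from
#'   [allelic_ratio_table()] (its cDNA rows are classified on
#'   `normalized_ratio`).
#' @param lower,upper Classification thresholds, `0 < lower < 1 < upper`.
#' @return For numeric input, a factor with levels `balanced`,
#'   `ase_allele1`, `ase_allele2`. For tibble input, an ASE-call tibble with
#'   `category`, `ratio_used` and the thresholds.
#' @export
classify_ase <- function(ratios, lower = 2 / 3, upper = 1.5) {
  if (!is.numeric(lower) || !is.numeric(upper) ||
      !(lower > 0 && lower < 1 && upper > 1)) {
    rlang::abort("thresholds must satisfy 0 < lower < 1 < upper",
                 class = "pyroase_config_error")
  }
  if (is.numeric(ratios)) {
    if (any(!is.finite(ratios) | ratios <= 0)) {
      rlang::abort("ratios must be positive and finite", class = "pyroase_domain_error")
    }
    cat <- ifelse(ratios > upper, "ase_allele1",
                  ifelse(ratios < lower, "ase_allele2", "balanced"))
    return(factor(cat, levels = c("balanced", "ase_allele1", "ase_allele2")))
  }
  stopifnot(is.data.frame(ratios), "normalized_ratio" %in% names(ratios))
  tbl <- tibble::as_tibble(ratios)
  if ("material" %in% names(tbl)) tbl <- tbl[tbl$material == "cDNA", , drop = FALSE]
  keep <- intersect(c("sample_id", "breed", "tissue", "gene"), names(tbl))
  dplyr::bind_cols(
    tbl[, keep, drop = FALSE],
    tibble::tibble(
      category = classify_ase(tbl$normalized_ratio, lower, upper),
      ratio_used = tbl$normalized_ratio,
      lower_threshold = lower,
      upper_threshold = upper))
}
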