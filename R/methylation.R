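# Per-CpG-site percent 5-methylcytosine summaries and comparisons between
# ASE and balanced (control) sample groups for configured CpG islands.

#' Define a CpG island configuration
#'
#' Islands are configuration, not discovered from sequence; coordinates are
#' 1-based inclusive throughout.
#'
#' @param island_id Identifier such as `"CGi1"`.
#' @param chrom Chromosome name (e.g. `"SSC8"`).
#' @param start,end 1-based inclusive island interval.
#' @param site_positions Strictly increasing CpG coordinates inside
#'   `[start, end]` for the assayed amplicon.
#' @return A list of class `cpg_island`.
#' @export
cpg_island <- function(island_id, chrom, start, end, site_positions) {
  stopifnot(start <= end)
  if (is.unsorted(site_positions, strictly = TRUE)) {
    rlang::abort("CpG site positions must be strictly increasing",
                 class = "pyroase_config_error")
  }
  if (any(site_positions < start | site_positions > end)) {
    rlang::abort("CpG site positions must lie within the island interval",
                 class = "pyroase_config_error")
  }
  structure(list(island_id = island_id, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 site_positions = as.integer(site_positions)),
            class = "cpg_island")
}

#' Select balanced control samples for the methylation comparison
#'
#' Controls are samples classified as balanced whose replicate-mean
#' normalized allelic ratio lies within `[1 - band, 1 + band]`, ordered by
#' closeness to 1 so the caller may truncate to a target group size. Mirrors
#' the study design where control groups had mean ratio +/- SD near 1.
#'
#' @param ase_calls ASE-call tibble from [classify_ase()].
#' @param ratios Ratio tibble from [allelic_ratio_table()] covering the same
#'   samples (cDNA rows are used).
#' @param band Half-width of the acceptance band around 1 (default 0.15).
#' @param n_max Optional cap on the number of controls returned.
#' @return Character vector of sample ids, sorted by `|ratio - 1|`.
#' @export
select_control_group <- function(ase_calls, ratios, band = 0.15, n_max = Inf) {
  stopifnot("category" %in% names(ase_calls), "sample_id" %in% names(ase_calls))
  if ("material" %in% names(ratios)) {
    ratios <- ratios[ratios$material == "cDNA", , drop = FALSE]
  }
  key <- intersect(c("sample_id", "gene", "tissue"), intersect(names(ase_calls), names(ratios)))
  merged <- dplyr::inner_join(
    ase_calls[, c(key, "category")],
    ratios[, c(key, "normalized_ratio")], by = key)
  ok <- merged$category == "balanced" &
    merged$normalized_ratio >= 1 - band & merged$normalized_ratio <= 1 + band
  sel <- merged[ok, , drop = FALSE]
  if (nrow(sel) == 0) {
    rlang::warn("no balanced samples within the control band")
    return(character())
  }
  sel <- sel[order(abs(sel$normalized_ratio - 1)), , drop = FALSE]
  utils::head(sel$sample_id, n_max)
}

#' Per-site methylation mean and SD for a sample group
#'
#' @param records Methylation tibble with columns `sample_id`, `position`,
#'   `pct_5mc` (and optionally `conversion_control_pass`, already filtered),
#'   restricted to one island x tissue.
#' @param group_ids Sample ids forming the group.
#' @param island A [cpg_island()]; records at positions outside its site
#'   list are rejected.
#' @return Tibble with one row per configured site: `position`, `mean_5mc`,
#'   `sd_5mc`, `n` (`n = 0` with `NA` mean for unmeasured sites).
#' @export
summarize_cpg <- function(records, group_ids, island) {
  stopifnot(inherits(island, "cpg_island"), length(group_ids) > 0)
  unknown <- setdiff(unique(records$position), island$site_positions)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("records at position(s) %s not in island '%s' config",
                         paste(unknown, collapse = ", "), island$island_id),
                 class = "pyroase_unknown_site")
  }
  grp <- records[records$sample_id %in% group_ids, , drop = FALSE]
  measured <- grp |>
    dplyr::group_by(position = .data$position) |>
    dplyr::summarise(
      mean_5mc = mean(.data$pct_5mc),
      sd_5mc = if (dplyr::n() > 1) stats::sd(.data$pct_5mc) else 0,
      n = dplyr::n(), .groups = "drop")
  tibble::tibble(position = island$site_positions) |>
    dplyr::left_join(measured, by = "position") |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' Compare per-CpG methylation between ASE and control groups
#'
#' At every configured CpG site, percent 5-mC of the ASE group is compared
#' with the control group by a two-sided Student t-test (classic pooled
#' equal-variance; Welch available via `welch = TRUE`). Sites with fewer
#' than 2 samples in either group are flagged not tested. Records failing
#' the bisulfite conversion control are excluded up front.
#'
#' @param ase_records,ctrl_records Methylation tibbles (columns `sample_id`,
#'   `position`, `pct_5mc`, optional `conversion_control_pass`) for one
#'   island x tissue.
#' @param island A [cpg_island()].
#' @param welch Use the unequal-variance test instead of pooled.
#' @return Tibble with one row per site: group means/SDs/ns, `t_statistic`,
#'   `p_value`, `tested`.
#' @export
compare_methylation <- function(ase_records, ctrl_records, island, welch = FALSE) {
  stopifnot(inherits(island, "cpg_island"))
  if (nrow(ase_records) == 0 || nrow(ctrl_records) == 0) {
    rlang::abort("both ASE and control groups must be non-empty",
                 class = "pyroase_insufficient_group")
  }
  drop_failed <- function(x) {
    if ("conversion_control_pass" %in% names(x)) {
      n_fail <- sum(!x$conversion_control_pass)
      if (n_fail > 0) {
        rlang::inform(sprintf("excluding %d record(s) failing the conversion control", n_fail))
      }
      x <- x[x$conversion_control_pass, , drop = FALSE]
    }
    x
  }
  ase_records <- drop_failed(ase_records)
  ctrl_records <- drop_failed(ctrl_records)

  a <- summarize_cpg(ase_records, unique(ase_records$sample_id), island)
  ctl <- summarize_cpg(ctrl_records, unique(ctrl_records$sample_id), island)

  out <- vector("list", length(island$site_positions))
  for (i in seq_along(island$site_positions)) {
    pos <- island$site_positions[i]
    av <- ase_records$pct_5mc[ase_records$position == pos]
    cv <- ctrl_records$pct_5mc[ctrl_records$position == pos]
    tested <- length(av) >= 2 && length(cv) >= 2
    tstat <- p <- NA_real_
    if (tested) {
      if (stats::var(av) == 0 && stats::var(cv) == 0) {
        tstat <- 0
        p <- 1
      } else {
        ht <- stats::t.test(av, cv, var.equal = !welch, alternative = "two.sided")
        tstat <- unname(ht$statistic)
        p <- ht$p.value
      }
    }
    out[[i]] <- tibble::tibble(
      island_id = island$island_id, position = pos,
      mean_ase = a$mean_5mc[i], sd_ase = a$sd_5mc[i], n_ase = length(av),
      mean_ctrl = ctl$mean_5mc[i], sd_ctrl = ctl$sd_5mc[i], n_ctrl = length(cv),
      t_statistic = tstat, p_value = p, tested = tested)
  }
  dplyr::bind_rows(out)
}

#' Export tested CpG sites as BED intervals
#'
#' Converts 1-based inclusive site coordinates to 0-based half-open BED
#' lines, one per configured site.
#'
#' @param island A [cpg_island()].
#' @param path Output file path.
#' @return Invisibly, the BED tibble written.
#' @export
write_sites_bed <- function(island, path) {
  stopifnot(inherits(island, "cpg_island"))
  bed <- tibble::tibble(
    chrom = island$chrom,
    start = island$site_positions - 1L,
    end = island$site_positions,
    name = sprintf("%s_CpG%d", island$island_id, seq_along(island$site_positions)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
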