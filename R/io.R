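# Readers and writers for the pipeline's plain-text dialects. All tables
# are UTF-8 TSV with a header row and '.' for missing; genotypes may come
# from a VCF 4.2 instead. Invalid rows are never silently dropped: they are
# returned as an exclusion table with machine-readable reason codes.

# All columns read as character ('T' alleles and 'A/T' genotypes must never
# be parsed as logicals), then coerced per dialect by the callers.
.read_tsv <- function(path, numeric_cols = character(),
                      integer_cols = character(), logical_cols = character()) {
  x <- tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                           na.strings = ".",
                                           colClasses = "character",
                                           check.names = FALSE))
  for (col in intersect(numeric_cols, names(x))) x[[col]] <- as.numeric(x[[col]])
  for (col in intersect(integer_cols, names(x))) x[[col]] <- as.integer(x[[col]])
  for (col in intersect(logical_cols, names(x))) x[[col]] <- as.logical(x[[col]])
  x
}

#' Write a pipeline TSV ('.' for missing)
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_pyro_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Validate replicate-level pyrosequencing measurements
#'
#' Checks required fields, the percentage range (0, 100) exclusive of the
#' endpoints (0% or 100% in a heterozygote indicates a failed assay), the
#' pairwise sum-to-100 tolerance, and distinct allele labels. Valid and
#' rejected rows are partitioned; every rejected row carries a reason code.
#'
#' @param measurements Tibble with columns `sample_id`, `breed`, `tissue`,
#'   `gene`, `material`, `allele1`, `allele2`, `pct_allele1`, `pct_allele2`,
#'   `replicate`.
#' @param sum_tol Tolerance on `pct_allele1 + pct_allele2 - 100`.
#' @return List with `valid` (tibble) and `excluded` (tibble with columns of
#'   the input plus `reason`).
#' @export
validate_measurements <- function(measurements, sum_tol = 0.5) {
  required <- c("sample_id", "breed", "tissue", "gene", "material",
                "allele1", "allele2", "pct_allele1", "pct_allele2", "replicate")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("measurement table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 class = "pyroase_format_error")
  }
  m <- tibble::as_tibble(measurements)
  reason <- rep(NA_character_, nrow(m))
  has_na <- Reduce(`|`, lapply(m[required], is.na))
  reason[has_na] <- "missing_required_field"
  p1 <- m$pct_allele1; p2 <- m$pct_allele2
  bad_mat <- is.na(reason) & !m$material %in% c("cDNA", "gDNA")
  reason[bad_mat] <- "unknown_material"
  same_allele <- is.na(reason) & m$allele1 == m$allele2
  reason[same_allele] <- "identical_allele_labels"
  out_rng <- is.na(reason) & (p1 <= 0 | p2 <= 0 | p1 >= 100 | p2 >= 100)
  reason[out_rng] <- "percentage_out_of_range"
  off <- is.na(reason) & abs(p1 + p2 - 100) > sum_tol
  reason[off] <- "percentages_do_not_sum_to_100"
  list(valid = m[is.na(reason), , drop = FALSE],
       excluded = dplyr::mutate(m[!is.na(reason), , drop = FALSE],
                                reason = reason[!is.na(reason)]))
}

#' Read a replicate-level pyrosequencing measurement TSV
#'
#' @param path TSV path (columns as in [validate_measurements()]).
#' @inheritParams validate_measurements
#' @return List with `valid` and `excluded` tibbles.
#' @export
read_pyro_tsv <- function(path, sum_tol = 0.5) {
  tbl <- .read_tsv(path,
                   numeric_cols = c("pct_allele1", "pct_allele2"),
                   integer_cols = "replicate")
  validate_measurements(tbl, sum_tol = sum_tol)
}

#' Read a genotype TSV
#'
#' @param path TSV with columns `sample_id`, `breed`, `gene` (or `snp_id`),
#'   `genotype` as `"A/G"`-style strings.
#' @return Tibble.
#' @export
read_genotypes_tsv <- function(path) {
  g <- .read_tsv(path)
  stopifnot(all(c("sample_id", "genotype") %in% names(g)))
  g
}

#' Read genotypes from a VCF (4.2, GT field)
#'
#' Converts each biallelic record's GT calls to `"A/G"`-style allele
#' strings; multi-allelic records are rejected.
#'
#' @param path VCF path.
#' @return Tibble with `sample_id`, `snp_id`, `chrom`, `pos`, `genotype`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    rlang::abort("package 'vcfR' is required to read VCF genotype input",
                 class = "pyroase_format_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- if (is.null(dim(fix))) t(fix) else fix
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt))) {
    rlang::abort("multi-allelic VCF records are not supported",
                 class = "pyroase_format_error")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alleles <- c(fix[i, "REF"], alt[i])
    calls <- gt[i, ]
    idx <- strsplit(gsub("\\|", "/", calls), "/")
    geno <- unname(vapply(idx, function(ab) {
      if (length(ab) != 2 || any(ab == ".")) return(NA_character_)
      paste(alleles[as.integer(ab) + 1], collapse = "/")
    }, character(1)))
    rows[[i]] <- tibble::tibble(
      sample_id = colnames(gt), snp_id = fix[i, "ID"],
      chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
      genotype = geno)
  }
  dplyr::bind_rows(rows)
}

#' Read a per-CpG methylation TSV
#'
#' @param path TSV with columns `sample_id`, `tissue`, `island_id`, `chrom`,
#'   `position` (1-based), `pct_5mc`, `conversion_control_pass`.
#' @return Tibble with logical `conversion_control_pass`.
#' @export
read_methylation_tsv <- function(path) {
  m <- .read_tsv(path, numeric_cols = "pct_5mc", integer_cols = "position",
                 logical_cols = "conversion_control_pass")
  stopifnot(all(c("sample_id", "tissue", "island_id", "position", "pct_5mc")
                %in% names(m)))
  m
}
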