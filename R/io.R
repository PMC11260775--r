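# Reading, validating and writing GWAS summary-statistic and annotation tables.
#
# The internal column standard is:
#   rsid, chrom, pos, effect_allele, other_allele, beta, se, pval, eaf, n
# `eaf` and `n` are optional at read time; operations that need the effect
# allele frequency (palindromic inference, variance explained) raise an
# explicit error when it is missing.

MR_COLUMNS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "pval", "eaf", "n")
MR_MANDATORY <- setdiff(MR_COLUMNS, c("eaf", "n"))

#' Default trait-category vocabulary for SNP annotations
#'
#' Categories used to group secondary trait associations of the instruments
#' (as returned by a phenome-wide lookup) for the category-exclusion
#' sensitivity analyses.
#'
#' @return Character vector of category labels.
#' @export
mr_trait_categories <- function() {
  c("lipid", "blood", "inflammation", "body_composition",
    "type_2_diabetes", "other")
}

#' Validate a data frame of GWAS summary statistics
#'
#' Applies the per-row invariants (single-nucleotide alleles, distinct
#' effect/other allele, `se > 0`, `pval` in (0, 1], `eaf` in (0, 1) when
#' present, unique `rsid`), upper-cases alleles, and sorts accepted rows by
#' `(chrom, pos)`. Rows failing an invariant are removed, never silently:
#' they are returned in the `rejected` attribute with a per-row reason and
#' reported via a warning naming the offending rsids.
#'
#' @param x A data frame with the internal standard columns (see
#'   [read_summary_stats()] for adapting other dialects).
#' @param trait_label Optional label describing the trait.
#' @param n_total Optional total sample size of the study.
#' @return A tibble of accepted records with attributes `trait_label`,
#'   `n_total` and `rejected` (tibble with columns `rsid`, `row`, `reason`).
#' @export
as_summary_stats <- function(x, trait_label = NULL, n_total = NULL) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(MR_MANDATORY, names(x))
  if (length(missing_cols) > 0) {
    stop_config(paste0("missing mandatory column(s): ", fmt_ids(missing_cols)))
  }
  if (!"eaf" %in% names(x)) x$eaf <- NA_real_
  if (!"n" %in% names(x)) x$n <- NA_integer_
  x <- x[MR_COLUMNS]

  x$rsid <- as.character(x$rsid)
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  x$beta <- as.numeric(x$beta)
  x$se <- as.numeric(x$se)
  x$pval <- as.numeric(x$pval)
  x$eaf <- as.numeric(x$eaf)
  x$n <- as.integer(x$n)

  reason <- rep(NA_character_, nrow(x))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    ifelse(is.na(reason) & bad, why, reason)
  }
  nuc <- c("A", "C", "G", "T")
  reason <- flag(is.na(x$rsid) | x$rsid == "", "missing rsid")
  reason <- flag(is.na(x$pos), "missing position")
  reason <- flag(!(x$effect_allele %in% nuc), "effect allele not a single nucleotide")
  reason <- flag(!(x$other_allele %in% nuc), "other allele not a single nucleotide")
  reason <- flag(x$effect_allele == x$other_allele, "identical alleles")
  reason <- flag(!is.finite(x$beta), "missing beta")
  reason <- flag(!is.finite(x$se) | x$se <= 0, "se not > 0")
  reason <- flag(!is.finite(x$pval) | x$pval <= 0 | x$pval > 1, "pval outside (0, 1]")
  eaf_bad <- !is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1)
  reason <- ifelse(is.na(reason) & eaf_bad, "eaf outside (0, 1)", reason)
  dup <- duplicated(x$rsid) & !is.na(x$rsid)
  reason <- ifelse(is.na(reason) & dup, "duplicate rsid", reason)

  rejected <- tibble::tibble(
    rsid = x$rsid[!is.na(reason)],
    row = which(!is.na(reason)),
    reason = reason[!is.na(reason)]
  )
  accepted <- x[is.na(reason), , drop = FALSE]
  accepted <- accepted[order_by(accepted$chrom, accepted$pos, accepted$rsid), ]

  if (nrow(rejected) > 0) {
    warn(paste0(nrow(rejected), " row(s) rejected during validation: ",
                fmt_ids(paste0(rejected$rsid, " (", rejected$reason, ")"))))
  }
  attr(accepted, "trait_label") <- trait_label
  attr(accepted, "n_total") <- n_total
  attr(accepted, "rejected") <- rejected
  accepted
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' @param path Path to a TSV file.
#' @param dialect Optional named character vector mapping internal column
#'   names to the file's column names, e.g.
#'   `c(rsid = "SNP", pval = "p_value")`. Unmapped columns are assumed to
#'   already use the internal names.
#' @inheritParams as_summary_stats
#' @return A validated summary-statistics tibble; see [as_summary_stats()].
#' @export
read_summary_stats <- function(path, dialect = NULL, trait_label = NULL,
                               n_total = NULL) {
  if (!file.exists(path)) stop_config(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(dialect)) {
    bad <- setdiff(unname(dialect), names(raw))
    if (length(bad) > 0) {
      stop_config(paste0("dialect maps to absent column(s): ", fmt_ids(bad)))
    }
    for (internal in names(dialect)) {
      names(raw)[names(raw) == dialect[[internal]]] <- internal
    }
  }
  as_summary_stats(raw, trait_label = trait_label, n_total = n_total)
}

#' Write a summary-statistics table to TSV
#'
#' Inverse of [read_summary_stats()]; writing then re-reading a valid table
#' reproduces it.
#'
#' @param x Summary-statistics tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x)[intersect(MR_COLUMNS, names(x))], path,
                   progress = FALSE)
  invisible(path)
}

#' Read or validate a SNP-to-trait-category annotation table
#'
#' The table has two columns, `rsid` and `category`, one row per
#' SNP-category pair. Duplicate pairs (the same association reported by
#' several source GWAS) are collapsed to one.
#'
#' @param path Path to a two-column TSV.
#' @param categories Declared category vocabulary; a category outside it is
#'   a configuration error.
#' @return Tibble with columns `rsid`, `category`, one row per distinct pair.
#' @export
read_annotations <- function(path, categories = mr_trait_categories()) {
  if (!file.exists(path)) stop_config(paste0("file not found: ", path))
  if (file.size(path) == 0) {
    return(tibble::tibble(rsid = character(), category = character()))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  as_trait_annotations(raw, categories = categories)
}

#' @rdname read_annotations
#' @param x Data frame with columns `rsid` and `category`.
#' @export
as_trait_annotations <- function(x, categories = mr_trait_categories()) {
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) {
    return(tibble::tibble(rsid = character(), category = character()))
  }
  if (!all(c("rsid", "category") %in% names(x))) {
    stop_config("annotation table must have columns `rsid` and `category`")
  }
  x$rsid <- as.character(x$rsid)
  x$category <- as.character(x$category)
  unknown <- setdiff(unique(x$category), categories)
  if (length(unknown) > 0) {
    stop_config(paste0("undeclared trait categor(ies): ", fmt_ids(unknown)))
  }
  dplyr::distinct(x[c("rsid", "category")])
}

#' Write MR results to disk
#'
#' Writes a deterministic 8-column TSV of per-method causal estimates
#' (`method`, `n_snp`, `beta`, `se`, `or`, `or_ci_low`, `or_ci_high`,
#' `pval`) plus, when supplied, a machine-readable JSON report of the
#' sensitivity analyses. Output is byte-identical across runs on identical
#' inputs.
#'
#' @param estimates Tibble of estimates as returned by [mr_all_methods()].
#' @param dir Output directory (created if absent).
#' @param sensitivity Optional list of sensitivity results to serialize.
#' @return Character vector of files written, invisibly.
#' @export
write_mr_results <- function(estimates, dir, sensitivity = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cols <- c("method", "n_snp", "beta", "se", "or", "or_ci_low",
            "or_ci_high", "pval")
  est <- tibble::as_tibble(estimates)
  for (cc in setdiff(cols, names(est))) est[[cc]] <- NA_real_
  est_path <- file.path(dir, "mr_estimates.tsv")
  readr::write_tsv(est[cols], est_path, progress = FALSE)
  written <- est_path
  if (!is.null(sensitivity)) {
    json_path <- file.path(dir, "mr_report.json")
    jsonlite::write_json(sensitivity, json_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE,
                         force = TRUE)
    written <- c(written, json_path)
  }
  invisible(written)
}
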