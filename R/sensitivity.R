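# Heterogeneity, directional pleiotropy, leave-one-out and trait-category
# exclusion sensitivity analyses.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (theta_j - theta_ivw)^2` over the per-SNP Wald ratios
#' `theta_j`, with inverse-variance weights `w_j = beta_exposure^2 /
#' se_outcome^2`; under homogeneity Q follows a chi-square distribution
#' with `J - 1` degrees of freedom. Q is zero exactly when all ratios
#' coincide.
#'
#' @param dat Harmonized instrument tibble (at least 2 SNPs).
#' @return One-row tibble (`q_stat`, `q_df`, `q_pval`).
#' @export
mr_cochran_q <- function(dat) {
  check_harmonized(dat, 2L, "Cochran's Q")
  fit <- mr_ivw(dat, model = "fixed")
  tibble::tibble(
    q_stat = fit$extras$q_stat,
    q_df = fit$extras$q_df,
    q_pval = fit$extras$q_pval
  )
}

#' Egger-intercept test for directional pleiotropy
#'
#' @param dat Harmonized instrument tibble (at least 3 SNPs).
#' @return One-row tibble (`egger_intercept`, `se`, `pval`).
#' @export
mr_pleiotropy_test <- function(dat) {
  fit <- mr_egger(dat)
  tibble::tibble(
    egger_intercept = fit$extras$intercept %||% NA_real_,
    se = fit$extras$intercept_se %||% NA_real_,
    pval = fit$extras$intercept_pval %||% NA_real_
  )
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW effect with each instrument removed in turn, to
#' expose estimates driven by a single SNP.
#'
#' @param dat Harmonized instrument tibble (at least 3 SNPs).
#' @param model IVW model, see [mr_ivw()].
#' @return Tibble with one row per left-out SNP (`rsid`, `n_snp`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `pval`).
#' @export
mr_leave_one_out <- function(dat, model = "random") {
  check_harmonized(dat, 3L, "leave-one-out")
  purrr::map_dfr(seq_len(nrow(dat)), function(j) {
    fit <- mr_ivw(dat[-j, , drop = FALSE], model = model)
    tibble::tibble(rsid = dat$rsid[j], n_snp = fit$nsnp, beta = fit$b,
                   se = fit$se, ci_low = fit$ci_low, ci_high = fit$ci_high,
                   pval = fit$pval)
  })
}

#' Trait-category exclusion (and keep-only) analyses
#'
#' For each trait category, removes (or, with `mode = "keep_only"`,
#' restricts to) the instruments annotated with it and re-runs the full
#' estimator battery plus Cochran's Q and the Egger-intercept test on the
#' reduced panel, through exactly the same code path as the main analysis.
#' A category that empties the instrument set is recorded as not
#' estimable, not an error.
#'
#' @param dat Harmonized instrument tibble.
#' @param annotations Tibble (`rsid`, `category`), see
#'   [read_annotations()].
#' @param categories Categories to analyse (default: every category
#'   present in `annotations` other than `"other"`).
#' @param mode `"exclude"` (drop annotated SNPs) or `"keep_only"`.
#' @param ... Passed to [mr_all_methods()] (`n_boot`, `seed`, ...).
#' @return Tibble of per-category, per-method estimates with columns
#'   `category`, `mode`, `n_excluded` plus the [tidy()] estimate columns;
#'   attribute `details` is a named list with each category's
#'   `estimates`, `q`, `pleiotropy` and `snps`, and `not_estimable` flags.
#' @export
mr_category_exclusion <- function(dat, annotations, categories = NULL,
                                  mode = c("exclude", "keep_only"), ...) {
  mode <- match.arg(mode)
  annotations <- tibble::as_tibble(annotations)
  categories <- categories %||% setdiff(sort(unique(annotations$category)),
                                        "other")
  details <- list()
  rows <- list()
  for (cat in categories) {
    hit <- annotations$rsid[annotations$category == cat]
    keep <- if (mode == "exclude") !(dat$rsid %in% hit) else dat$rsid %in% hit
    sub <- dat[keep, , drop = FALSE]
    n_removed <- nrow(dat) - nrow(sub)
    if (nrow(sub) == 0) {
      details[[cat]] <- list(not_estimable = TRUE, snps = character())
      rows[[cat]] <- tibble::tibble(category = cat, mode = mode,
                                    n_excluded = n_removed,
                                    method = NA_character_, n_snp = 0L)
      next
    }
    est <- mr_all_methods(sub, ...)
    q <- if (nrow(sub) >= 2) mr_cochran_q(sub) else NULL
    plt <- if (nrow(sub) >= 3) mr_pleiotropy_test(sub) else NULL
    details[[cat]] <- list(not_estimable = FALSE, estimates = est, q = q,
                           pleiotropy = plt, snps = sub$rsid)
    rows[[cat]] <- dplyr::mutate(est, category = cat, mode = mode,
                                 n_excluded = n_removed, .before = 1)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "details") <- details
  out
}
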