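# Allele harmonization of exposure and outcome records onto a common
# effect allele, and instrument-strength statistics.

STRAND_COMP <- c(A = "T", C = "G", G = "C", T = "A")

flip_strand <- function(a) unname(STRAND_COMP[a])

is_palindromic_pair <- function(a1, a2) !is.na(a1) & !is.na(a2) &
  unname(STRAND_COMP[a1]) == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns every rsid shared between the two tables onto the exposure's
#' effect allele. The exposure orientation is never altered; only outcome
#' records are flipped. For each shared SNP:
#'
#' * alleles identical: kept as-is;
#' * effect/other swapped in the outcome: outcome beta negated and
#'   `eaf_outcome` replaced by its complement;
#' * alleles match after strand complementation (A<->T, C<->G), with or
#'   without a swap: relabelled (and sign/frequency adjusted if swapped);
#' * palindromic pair (A/T or C/G): strand orientation cannot be read off
#'   the allele labels, so it is inferred from allele frequencies — only
#'   when the minor allele frequency is below `maf_threshold` in *both*
#'   studies; the orientation making the effect-allele frequencies
#'   concordant (same side of 0.5) is adopted, otherwise the SNP is
#'   dropped as ambiguous;
#' * irreconcilable allele sets: dropped as incompatible.
#'
#' @param exposure,outcome Validated summary-statistics tibbles. The
#'   outcome table may carry `is_proxy`/`proxy_rsid` columns from
#'   [substitute_proxies()].
#' @param maf_threshold MAF below which palindromic orientation is
#'   inferred from frequencies (default `0.3`).
#' @return Tibble of harmonized instrument pairs with columns `rsid`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta_exposure`,
#'   `se_exposure`, `eaf_exposure`, `pval_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_outcome`, `pval_outcome`, `is_proxy`,
#'   `proxy_rsid`, `action`; attribute `audit` itemizes every input
#'   exposure SNP as kept or dropped with a reason, so
#'   `n input = n kept + n dropped` always holds.
#' @export
harmonize <- function(exposure, outcome, maf_threshold = 0.3) {
  check_number(maf_threshold, "maf_threshold", 0, 0.5)
  ex <- tibble::as_tibble(exposure)
  ou <- tibble::as_tibble(outcome)
  if (!"is_proxy" %in% names(ou)) ou$is_proxy <- FALSE
  if (!"proxy_rsid" %in% names(ou)) ou$proxy_rsid <- NA_character_

  audit <- tibble::tibble(rsid = character(), action = character(),
                          reason = character())
  note <- function(rsid, action, reason = NA_character_) {
    audit <<- dplyr::bind_rows(audit, tibble::tibble(
      rsid = rsid, action = action, reason = reason))
  }

  pairs <- vector("list", nrow(ex))
  oidx <- match(ex$rsid, ou$rsid)
  for (i in seq_len(nrow(ex))) {
    j <- oidx[i]
    if (is.na(j)) {
      note(ex$rsid[i], "dropped", "absent_from_outcome")
      next
    }
    e <- ex[i, ]
    o <- ou[j, ]
    a1 <- e$effect_allele; a2 <- e$other_allele
    b1 <- o$effect_allele; b2 <- o$other_allele
    by <- o$beta; ey <- o$eaf
    act <- NULL

    if (is_palindromic_pair(a1, a2)) {
      # label alignment first (palindromic pairs are strand-invariant)
      if (b1 == a1 && b2 == a2) {
        # base orientation
      } else if (b1 == a2 && b2 == a1) {
        by <- -by
        ey <- if (is.na(ey)) NA_real_ else 1 - ey
      } else {
        note(e$rsid, "dropped", "incompatible_alleles")
        next
      }
      if (is.na(e$eaf) || is.na(ey)) {
        note(e$rsid, "dropped", "palindromic_no_eaf")
        next
      }
      maf_x <- min(e$eaf, 1 - e$eaf)
      maf_y <- min(ey, 1 - ey)
      if (maf_x >= maf_threshold || maf_y >= maf_threshold) {
        note(e$rsid, "dropped", "palindromic_ambiguous")
        next
      }
      if ((e$eaf < 0.5) != (ey < 0.5)) {
        # frequencies discordant: the outcome is reporting the complement
        # orientation; flip to make them concordant
        by <- -by
        ey <- 1 - ey
        act <- "palindromic_inferred_flipped"
      } else {
        act <- "palindromic_inferred"
      }
    } else {
      c1 <- flip_strand(b1); c2 <- flip_strand(b2)
      if (b1 == a1 && b2 == a2) {
        act <- "kept"
      } else if (b1 == a2 && b2 == a1) {
        by <- -by
        ey <- if (is.na(ey)) NA_real_ else 1 - ey
        act <- "flipped"
      } else if (c1 == a1 && c2 == a2) {
        act <- "strand_complemented"
      } else if (c1 == a2 && c2 == a1) {
        by <- -by
        ey <- if (is.na(ey)) NA_real_ else 1 - ey
        act <- "strand_complemented_flipped"
      } else {
        note(e$rsid, "dropped", "incompatible_alleles")
        next
      }
    }
    note(e$rsid, "kept", act)
    pairs[[i]] <- tibble::tibble(
      rsid = e$rsid, chrom = e$chrom, pos = e$pos,
      effect_allele = a1, other_allele = a2,
      beta_exposure = e$beta, se_exposure = e$se, eaf_exposure = e$eaf,
      pval_exposure = e$pval,
      beta_outcome = by, se_outcome = o$se, eaf_outcome = ey,
      pval_outcome = o$pval,
      is_proxy = isTRUE(o$is_proxy), proxy_rsid = o$proxy_rsid,
      action = act
    )
  }
  out <- dplyr::bind_rows(pairs)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      rsid = character(), chrom = character(), pos = integer(),
      effect_allele = character(), other_allele = character(),
      beta_exposure = numeric(), se_exposure = numeric(),
      eaf_exposure = numeric(), pval_exposure = numeric(),
      beta_outcome = numeric(), se_outcome = numeric(),
      eaf_outcome = numeric(), pval_outcome = numeric(),
      is_proxy = logical(), proxy_rsid = character(), action = character()
    )
  }
  attr(out, "audit") <- audit
  class(out) <- c("mr_harmonized", class(out))
  out
}

#' Summarize the harmonization audit trail
#'
#' @param harmonized Result of [harmonize()].
#' @return Tibble (`rsid`, `action`, `reason`).
#' @export
harmonization_audit <- function(harmonized) {
  attr(harmonized, "audit") %||%
    stop_config("no audit attribute; was this produced by harmonize()?")
}

#' Instrument strength: variance explained and F-statistic
#'
#' Per-SNP variance in the exposure explained by each instrument, from its
#' effect size (in SD units of the exposure) and minor allele frequency:
#' `r2_j = 2 * beta_j^2 * maf_j * (1 - maf_j)` under `formula =
#' "standard"`, or `beta_j^2 * maf_j * (1 - maf_j)` (no factor 2) under
#' `formula = "as_printed"`. The total `R2` is the sum over instruments and
#' the F-statistic is `(R2/k) / ((1 - R2)/(n - k - 1))` with `k` the number
#' of instruments.
#'
#' @param exposure Exposure summary-statistics or harmonized tibble (uses
#'   `beta`/`eaf`, or `beta_exposure`/`eaf_exposure`).
#' @param n Exposure GWAS sample size; defaults to the table's `n_total`
#'   attribute.
#' @param formula Variance-explained convention, see above.
#' @return Object of class `mr_strength`; `tidy()` gives the per-SNP
#'   table, `glance()` the totals (`r2_total`, `f_statistic`, `n_snp`, `n`).
#' @export
instrument_strength <- function(exposure, n = NULL,
                                formula = c("standard", "as_printed")) {
  formula <- match.arg(formula)
  ex <- tibble::as_tibble(exposure)
  pick <- function(a, b) {
    if (a %in% names(ex)) ex[[a]] else if (b %in% names(ex)) ex[[b]] else NULL
  }
  beta <- pick("beta", "beta_exposure")
  eaf <- pick("eaf", "eaf_exposure")
  if (is.null(beta) || is.null(eaf)) {
    stop_config("table must carry beta and eaf columns (exposure side)")
  }
  n <- n %||% attr(exposure, "n_total")
  if (is.null(n)) stop_config("exposure sample size `n` is required")
  check_number(n, "n", 2)
  if (any(is.na(eaf))) {
    stop_data(paste0("eaf missing for SNP(s): ", fmt_ids(ex$rsid[is.na(eaf)])))
  }
  maf <- pmin(eaf, 1 - eaf)
  fac <- if (formula == "standard") 2 else 1
  r2 <- fac * beta^2 * maf * (1 - maf)
  r2_total <- sum(r2)
  k <- length(r2)
  f <- mr_f_statistic(r2_total, n, k)
  structure(list(
    per_snp = tibble::tibble(rsid = ex$rsid, beta = beta, maf = maf, r2 = r2),
    r2_total = r2_total, f_statistic = f, n = n, n_snp = k,
    formula = formula
  ), class = "mr_strength")
}

#' F-statistic from total variance explained
#'
#' @param r2 Total variance in the exposure explained by the instruments.
#' @param n Exposure GWAS sample size.
#' @param k Number of instruments.
#' @return The F-statistic `(r2/k) / ((1 - r2)/(n - k - 1))`.
#' @export
mr_f_statistic <- function(r2, n, k) {
  check_number(r2, "r2", 0, 1, open_upper = TRUE)
  (r2 / k) / ((1 - r2) / (n - k - 1))
}

#' @method tidy mr_strength
#' @export
tidy.mr_strength <- function(x, ...) x$per_snp

#' @method glance mr_strength
#' @export
glance.mr_strength <- function(x, ...) {
  tibble::tibble(r2_total = x$r2_total, f_statistic = x$f_statistic,
                 n_snp = x$n_snp, n = x$n, formula = x$formula)
}

#' @export
print.mr_strength <- function(x, ...) {
  cat(sprintf(
    "Instrument strength: %d SNPs explain %.2f%% of exposure variance (F = %.1f)\n",
    x$n_snp, 100 * x$r2_total, x$f_statistic))
  invisible(x)
}
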