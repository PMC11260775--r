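# Linkage disequilibrium against a local reference panel: pairwise r^2,
# greedy p-value-ordered clumping, and proxy-SNP search.

#' Construct a linkage-disequilibrium reference panel
#'
#' A panel is backed either by an individuals-by-SNPs allele-dosage matrix
#' (values 0/1/2 counting one allele) with per-SNP metadata, or by
#' precomputed pairwise r-squared records with an allele-phase sign.
#'
#' @param genotypes Numeric matrix, rows = individuals, columns = SNPs,
#'   with rsids as column names; dosages of the counted allele.
#' @param info Data frame of SNP metadata with columns `rsid`, `chrom`,
#'   `pos`, `counted_allele`; required with `genotypes`.
#' @param r2_records Data frame with columns `rsid_a`, `rsid_b`, `r2`
#'   (in `[0, 1]`) and `sign` (+1/-1 phase of the counted alleles);
#'   alternative to `genotypes`. Pairs absent from the records are treated
#'   as unlinked (r^2 = 0). `info` is optional in this mode (positions are
#'   then unavailable for proxy-distance tie-breaks).
#' @return An object of class `ld_panel`.
#' @export
ld_panel <- function(genotypes = NULL, info = NULL, r2_records = NULL) {
  if (is.null(genotypes) == is.null(r2_records)) {
    stop_config("supply exactly one of `genotypes` or `r2_records`")
  }
  if (!is.null(genotypes)) {
    genotypes <- as.matrix(genotypes)
    storage.mode(genotypes) <- "double"
    if (is.null(colnames(genotypes))) {
      stop_config("genotype matrix must carry rsids as column names")
    }
    if (is.null(info)) stop_config("`info` metadata is required with genotypes")
    info <- tibble::as_tibble(info)
    need <- c("rsid", "chrom", "pos", "counted_allele")
    if (!all(need %in% names(info))) {
      stop_config(paste0("panel info must have columns: ", fmt_ids(need)))
    }
    info$rsid <- as.character(info$rsid)
    info$chrom <- as.character(info$chrom)
    info$pos <- as.integer(info$pos)
    info$counted_allele <- toupper(as.character(info$counted_allele))
    missing <- setdiff(colnames(genotypes), info$rsid)
    if (length(missing) > 0) {
      stop_config(paste0("panel SNP(s) lacking metadata: ", fmt_ids(missing)))
    }
    info <- info[match(colnames(genotypes), info$rsid), ]
    obj <- list(type = "genotypes", geno = genotypes, info = info)
  } else {
    r2_records <- tibble::as_tibble(r2_records)
    need <- c("rsid_a", "rsid_b", "r2")
    if (!all(need %in% names(r2_records))) {
      stop_config(paste0("r2 records must have columns: ", fmt_ids(need)))
    }
    if (!"sign" %in% names(r2_records)) r2_records$sign <- 1
    if (any(r2_records$r2 < 0 | r2_records$r2 > 1)) {
      stop_config("r2 values must lie in [0, 1]")
    }
    if (!all(r2_records$sign %in% c(-1, 1))) {
      stop_config("phase sign must be +1 or -1")
    }
    if (!is.null(info)) {
      info <- tibble::as_tibble(info)
      info$rsid <- as.character(info$rsid)
    }
    obj <- list(type = "records", records = r2_records, info = info)
  }
  structure(obj, class = "ld_panel")
}

#' Read a genotype-matrix LD panel from TSV files
#'
#' @param genotype_path TSV of dosages, one row per individual, one column
#'   per SNP, header row of rsids.
#' @param info_path Side-car metadata TSV (`rsid`, `chrom`, `pos`,
#'   `counted_allele`).
#' @return An `ld_panel`.
#' @export
read_ld_panel <- function(genotype_path, info_path) {
  for (p in c(genotype_path, info_path)) {
    if (!file.exists(p)) stop_config(paste0("file not found: ", p))
  }
  geno <- readr::read_tsv(genotype_path, show_col_types = FALSE, progress = FALSE)
  info <- readr::read_tsv(info_path, show_col_types = FALSE, progress = FALSE)
  ld_panel(genotypes = as.matrix(geno), info = info)
}

panel_has <- function(panel, rsids) {
  if (panel$type == "genotypes") {
    rsids %in% colnames(panel$geno)
  } else {
    hit <- rsids %in% c(panel$records$rsid_a, panel$records$rsid_b)
    if (!is.null(panel$info)) hit <- hit | rsids %in% panel$info$rsid
    hit
  }
}

panel_pos <- function(panel, rsid) {
  if (is.null(panel$info)) return(NA_integer_)
  i <- match(rsid, panel$info$rsid)
  if (is.na(i)) NA_integer_ else panel$info$pos[i]
}

# signed dosage correlation; NA when a pair is absent from r2 records
ld_r <- function(panel, a, b) {
  if (a == b) return(1)
  if (panel$type == "genotypes") {
    for (s in c(a, b)) {
      if (!(s %in% colnames(panel$geno))) {
        stop_data(paste0("SNP absent from LD panel: ", s))
      }
    }
    x <- panel$geno[, a]
    y <- panel$geno[, b]
    if (var(x) == 0 || var(y) == 0) {
      abort(paste0("LD undefined: monomorphic SNP among ", a, ", ", b),
            class = "mrkit_ld_error")
    }
    cor(x, y)
  } else {
    rec <- panel$records
    hit <- which((rec$rsid_a == a & rec$rsid_b == b) |
                   (rec$rsid_a == b & rec$rsid_b == a))
    if (length(hit) == 0) return(0)
    rec$sign[hit[1]] * sqrt(rec$r2[hit[1]])
  }
}

#' Pairwise linkage-disequilibrium r-squared
#'
#' Squared Pearson correlation of allele dosages in the reference panel
#' (composite LD on unphased dosages). Symmetric in its arguments;
#' `compute_r2(panel, a, a)` is 1.
#'
#' @param panel An [ld_panel()].
#' @param a,b rsids of the two SNPs.
#' @return r-squared in `[0, 1]`.
#' @export
compute_r2 <- function(panel, a, b) {
  ld_r(panel, a, b)^2
}

#' Greedy LD clumping of a summary-statistics table
#'
#' Restricts to SNPs below the significance threshold, then repeatedly
#' takes the remaining SNP with the smallest p-value as an index SNP and
#' discards all remaining SNPs on the same chromosome within the window
#' whose r-squared with the index exceeds the threshold. The retained SNPs
#' are mutually quasi-independent under these rules. Equal p-values are
#' broken by position, then rsid, so the result is deterministic.
#'
#' @param table Validated summary-statistics tibble.
#' @param panel An [ld_panel()].
#' @param p_threshold Genome-wide significance threshold (default `5e-8`).
#' @param r2_threshold LD pruning threshold (default `0.001`).
#' @param window_kb Half-window around the index SNP in kb (default
#'   `10000`, i.e. +/- 10,000 kb).
#' @param missing_snp Policy for significant SNPs absent from the panel:
#'   `"drop"` (default, conservative, with a warning) or `"unlinked"`
#'   (retain and treat as uncorrelated with everything).
#' @return The clumped table, ordered by ascending p-value, with attribute
#'   `clump_log` (tibble `rsid`, `status`, `index_rsid`).
#' @export
ld_clump <- function(table, panel, p_threshold = 5e-8, r2_threshold = 0.001,
                     window_kb = 10000, missing_snp = c("drop", "unlinked")) {
  missing_snp <- match.arg(missing_snp)
  check_number(p_threshold, "p_threshold", 0, 1, open_lower = TRUE)
  check_number(r2_threshold, "r2_threshold", 0, 1)
  check_number(window_kb, "window_kb", 0)
  tab <- tibble::as_tibble(table)
  sig <- tab[tab$pval < p_threshold, , drop = FALSE]
  log <- tibble::tibble(rsid = character(), status = character(),
                        index_rsid = character())
  present <- panel_has(panel, sig$rsid)
  if (any(!present)) {
    absent <- sig$rsid[!present]
    if (missing_snp == "drop") {
      warn(paste0("dropping ", length(absent),
                  " significant SNP(s) absent from the LD panel: ",
                  fmt_ids(absent)))
      log <- dplyr::bind_rows(log, tibble::tibble(
        rsid = absent, status = "absent_from_panel", index_rsid = NA_character_))
      sig <- sig[present, , drop = FALSE]
    }
  }
  ord <- order_by(sig$pval, sig$pos, sig$rsid)
  sig <- sig[ord, ]
  alive <- rep(TRUE, nrow(sig))
  keep <- logical(nrow(sig))
  unlinked <- !panel_has(panel, sig$rsid) # only possible under "unlinked"
  window_bp <- window_kb * 1000
  for (i in seq_len(nrow(sig))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    if (unlinked[i]) next
    cand <- which(alive & sig$chrom == sig$chrom[i] &
                    abs(sig$pos - sig$pos[i]) <= window_bp & !unlinked)
    for (j in cand) {
      if (compute_r2(panel, sig$rsid[i], sig$rsid[j]) > r2_threshold) {
        alive[j] <- FALSE
        log <- dplyr::bind_rows(log, tibble::tibble(
          rsid = sig$rsid[j], status = "clumped", index_rsid = sig$rsid[i]))
      }
    }
  }
  out <- sig[keep, , drop = FALSE]
  log <- dplyr::bind_rows(
    tibble::tibble(rsid = out$rsid, status = "index", index_rsid = out$rsid),
    log
  )
  attr(out, "trait_label") <- attr(table, "trait_label")
  attr(out, "n_total") <- attr(table, "n_total")
  attr(out, "clump_log") <- log
  out
}

#' Find a proxy SNP in high LD with a target SNP
#'
#' Among the candidate SNPs (typically those measured in the outcome
#' study), returns the one with maximal r-squared with the target, provided
#' it reaches `min_r2`. Ties are broken by smaller genomic distance to the
#' target, then lexicographic rsid. The phase sign of the dosage
#' correlation maps the proxy's counted allele onto the target's counted
#' allele.
#'
#' @param panel An [ld_panel()].
#' @param target rsid of the missing instrument.
#' @param candidates Character vector of candidate rsids.
#' @param min_r2 Minimum acceptable r-squared (default `0.8`).
#' @return One-row tibble (`target`, `proxy`, `r2`, `sign`, `distance`),
#'   or `NULL` when no candidate qualifies.
#' @export
find_proxy <- function(panel, target, candidates, min_r2 = 0.8) {
  check_number(min_r2, "min_r2", 0, 1)
  if (!panel_has(panel, target)) return(NULL)
  candidates <- setdiff(unique(candidates), target)
  candidates <- candidates[panel_has(panel, candidates)]
  if (length(candidates) == 0) return(NULL)
  rr <- vapply(candidates, function(s) {
    tryCatch(ld_r(panel, target, s), mrkit_ld_error = function(e) NA_real_)
  }, numeric(1))
  r2 <- rr^2
  ok <- !is.na(r2) & r2 >= min_r2
  if (!any(ok)) return(NULL)
  tpos <- panel_pos(panel, target)
  dist <- vapply(candidates, function(s) {
    p <- panel_pos(panel, s)
    if (is.na(p) || is.na(tpos)) Inf else abs(p - tpos)
  }, numeric(1))
  idx <- which(ok)
  best <- idx[order_by(-r2[idx], dist[idx], candidates[idx])][1]
  tibble::tibble(
    target = target,
    proxy = candidates[best],
    r2 = unname(r2[best]),
    sign = unname(sign(rr[best])),
    distance = unname(dist[best])
  )
}

#' Substitute proxies for instruments missing from the outcome study
#'
#' For every exposure instrument absent from the outcome table, searches
#' the panel for a proxy among the outcome SNPs at `min_r2` or above and,
#' when found, constructs an outcome-side record for the target rsid from
#' the proxy's association, with alleles mapped through the LD phase so the
#' proxy's effect corresponds to the target's effect allele.
#'
#' @param exposure Exposure instrument table (post-clumping).
#' @param outcome Outcome summary-statistics table.
#' @param panel An [ld_panel()].
#' @param min_r2 Minimum proxy r-squared (default `0.8`).
#' @return The outcome table augmented with proxy-derived records (columns
#'   `is_proxy`, `proxy_rsid`, `proxy_r2` added), with attribute
#'   `proxy_log` (tibble `target`, `proxy`, `r2`, `status`).
#' @export
substitute_proxies <- function(exposure, outcome, panel, min_r2 = 0.8) {
  out <- tibble::as_tibble(outcome)
  out$is_proxy <- FALSE
  out$proxy_rsid <- NA_character_
  out$proxy_r2 <- NA_real_
  targets <- setdiff(exposure$rsid, out$rsid)
  log <- tibble::tibble(target = character(), proxy = character(),
                        r2 = numeric(), status = character())
  add_log <- function(target, proxy, r2, status) {
    dplyr::bind_rows(log, tibble::tibble(target = target, proxy = proxy,
                                         r2 = r2, status = status))
  }
  for (tg in targets) {
    m <- find_proxy(panel, tg, out$rsid[!out$is_proxy], min_r2 = min_r2)
    if (is.null(m)) {
      log <- add_log(tg, NA_character_, NA_real_, "no_proxy")
      next
    }
    erow <- exposure[exposure$rsid == tg, ]
    prow <- out[out$rsid == m$proxy, ][1, ]
    ct <- panel_counted(panel, tg)
    cp <- panel_counted(panel, m$proxy)
    if (is.na(ct) || is.na(cp) ||
        !(ct %in% c(erow$effect_allele, erow$other_allele))) {
      log <- add_log(tg, m$proxy, m$r2, "allele_mismatch")
      next
    }
    # orient the proxy record to its counted allele (strand complements allowed)
    aligned <- align_to_counted(prow, cp)
    if (is.null(aligned)) {
      log <- add_log(tg, m$proxy, m$r2, "allele_mismatch")
      next
    }
    b <- aligned$beta
    e <- aligned$eaf
    if (m$sign < 0) { # target counted allele travels with the proxy's other allele
      b <- -b
      e <- if (is.na(e)) NA_real_ else 1 - e
    }
    other_t <- setdiff(c(erow$effect_allele, erow$other_allele), ct)
    new_row <- tibble::tibble(
      rsid = tg, chrom = erow$chrom, pos = erow$pos,
      effect_allele = ct, other_allele = other_t,
      beta = b, se = prow$se, pval = prow$pval, eaf = e, n = prow$n,
      is_proxy = TRUE, proxy_rsid = m$proxy, proxy_r2 = m$r2
    )
    out <- dplyr::bind_rows(out, new_row)
    log <- add_log(tg, m$proxy, m$r2, "substituted")
  }
  attr(out, "trait_label") <- attr(outcome, "trait_label")
  attr(out, "n_total") <- attr(outcome, "n_total")
  attr(out, "proxy_log") <- log
  out
}

panel_counted <- function(panel, rsid) {
  if (is.null(panel$info) || !"counted_allele" %in% names(panel$info)) {
    return(NA_character_)
  }
  i <- match(rsid, panel$info$rsid)
  if (is.na(i)) NA_character_ else panel$info$counted_allele[i]
}

# express a summary record's effect for a given counted allele;
# tolerates the record being reported on the opposite strand
align_to_counted <- function(row, counted) {
  comp <- flip_strand(counted)
  if (row$effect_allele == counted) {
    list(beta = row$beta, eaf = row$eaf)
  } else if (row$other_allele == counted) {
    list(beta = -row$beta, eaf = if (is.na(row$eaf)) NA_real_ else 1 - row$eaf)
  } else if (row$effect_allele == comp) {
    list(beta = row$beta, eaf = row$eaf)
  } else if (row$other_allele == comp) {
    list(beta = -row$beta, eaf = if (is.na(row$eaf)) NA_real_ else 1 - row$eaf)
  } else {
    NULL
  }
}
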