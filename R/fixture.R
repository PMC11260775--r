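# A deterministic synthetic study exercising every pipeline stage with a
# known instrument accounting: 52 conditionally independent exposure
# signals, of which 48 are measured in the outcome study and 2 more are
# recoverable through proxies in high LD, while harmonization removes 7
# frequency-ambiguous palindromic SNPs and 1 SNP with incompatible
# alleles, leaving 42 instruments.

#' Simulate the benchmark two-sample study
#'
#' Builds a complete synthetic study (exposure and outcome summary
#' statistics, genotype reference panel, trait-category annotations,
#' generating truth) whose instrument accounting is fixed by
#' construction, whatever the seed:
#'
#' * 82 exposure SNPs, of which 72 reach genome-wide significance and
#'   clump to 52 independent signals (20 regions carry a correlated
#'   satellite that is clumped away);
#' * 48 of the 52 signal regions are measured in the outcome study; 2 of
#'   the 4 missing ones have a planted proxy at r^2 >= 0.8 (one with
#'   negative LD phase), one has only a weak r^2 ~ 0.15 proxy, one has
#'   none;
#' * 7 signals are palindromic with minor allele frequency >= 0.3 in both
#'   studies (dropped as ambiguous), 3 further palindromic signals have
#'   MAF ~ 0.15 and are frequency-inferable (kept), and 1 signal has
#'   irreconcilable alleles (dropped), leaving 42 instruments;
#' * the outcome records cycle through direct, swapped, strand-complement
#'   and complement-plus-swap representations;
#' * the true causal effect is `theta`, with balanced pleiotropy on all
#'   instruments plus four large-offset outlier instruments, so the
#'   heterogeneity, pleiotropy and outlier diagnostics have signal;
#' * every category of [mr_trait_categories()] is represented in the
#'   annotation table, enabling all exclusion and keep-only analyses.
#'
#' @param seed Integer seed controlling the random draws (effect sizes,
#'   frequencies, sampling noise, panel genotypes); the instrument
#'   accounting does not depend on it.
#' @param theta True causal log-odds per SD (default `log(0.92)`).
#' @return An object of class `mr_simulation`; see [simulate_mr_study()].
#' @export
simulate_benchmark_study <- function(seed = 104L, theta = log(0.92)) {
  withr::local_seed(as.integer(seed))

  n_region <- 52L
  n_exposure <- 114999L
  n_case <- 9358L
  n_control <- 15482L
  v_eff <- n_case * n_control / (n_case + n_control)

  # region layout: far apart so clumping windows never span two regions
  chrom <- as.character(((seq_len(n_region) - 1) %% 22) + 1)
  region_round <- (seq_len(n_region) - 1) %/% 22
  pos <- as.integer(2e7 + region_round * 4e7)
  rsid <- sprintf("rs%04d", 1000 + seq_len(n_region))

  # region roles
  ambiguous <- 1:7       # palindromic, MAF >= 0.3 in both studies
  inferable <- 8:10      # palindromic, MAF ~ 0.15, frequency-resolvable
  incompat <- 11L        # outcome reports an irreconcilable allele pair
  plain <- 12:48         # ordinary regions, various representations
  proxied <- 49:50       # absent from outcome, good proxy available
  unproxied <- 51:52     # absent from outcome, no adequate proxy
  satellite_regions <- 12:31
  outlier_regions <- c(20L, 25L, 30L, 35L)

  # allele frequencies (exposure effect allele)
  eaf <- runif(n_region, 0.10, 0.28)
  eaf[ambiguous] <- runif(length(ambiguous), 0.36, 0.47)
  eaf[inferable] <- runif(length(inferable), 0.12, 0.20)
  maf <- pmin(eaf, 1 - eaf)

  # instrument effects and pleiotropy
  gam <- (0.078 + abs(rnorm(n_region, 0, 0.012))) *
    sample(c(-1, 1), n_region, replace = TRUE)
  delta <- rnorm(n_region, 0, 0.03)
  delta[outlier_regions] <- sample(c(-1, 1), 4, replace = TRUE) * 0.15

  # alleles
  ea <- oa <- character(n_region)
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  np_pairs <- list(c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
                   c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T"))
  pal_regions <- c(ambiguous, inferable)
  for (i in seq_len(n_region)) {
    p <- if (i %in% pal_regions) {
      pal_pairs[[(i %% 4) + 1]]
    } else {
      np_pairs[[(i %% 8) + 1]]
    }
    ea[i] <- p[1]
    oa[i] <- p[2]
  }

  se_x <- 1 / sqrt(2 * n_exposure * eaf * (1 - eaf))
  se_y <- 1 / sqrt(2 * v_eff * eaf * (1 - eaf))
  beta_x <- rnorm(n_region, gam, se_x)
  Gamma_true <- theta * gam + delta
  beta_y <- rnorm(n_region, Gamma_true, se_y)
  eaf_y <- pmin(pmax(eaf + rnorm(n_region, 0, 0.008), 0.02), 0.98)
  # keep the ambiguity/inferability classification immune to frequency noise
  eaf_y[ambiguous] <- pmin(pmax(eaf_y[ambiguous], 0.32), 0.68)
  eaf_y[inferable] <- pmin(pmax(eaf_y[inferable], 0.05), 0.28)

  index_tbl <- tibble::tibble(
    rsid = rsid, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa,
    beta = beta_x, se = se_x,
    pval = pmax(2 * pnorm(-abs(beta_x / se_x)), 1e-300),
    eaf = eaf, n = n_exposure
  )

  # correlated satellites, clumped away in the exposure
  sat_region <- satellite_regions
  sat_r <- 0.94
  sat_rsid <- sprintf("rs%04d", 1500 + seq_along(sat_region))
  sat_beta <- sat_r * beta_x[sat_region] +
    sqrt(1 - sat_r^2) * rnorm(length(sat_region), 0, se_x[sat_region])
  sat_tbl <- tibble::tibble(
    rsid = sat_rsid, chrom = chrom[sat_region],
    pos = pos[sat_region] + 30000L,
    effect_allele = ea[sat_region], other_allele = oa[sat_region],
    beta = sat_beta, se = se_x[sat_region],
    pval = pmax(2 * pnorm(-abs(sat_beta / se_x[sat_region])), 1e-300),
    eaf = eaf[sat_region], n = n_exposure
  )

  # sub-threshold SNPs removed at the significance filter
  ns_rsid <- sprintf("rs%04d", 1900 + 1:10)
  ns_maf <- runif(10, 0.1, 0.4)
  ns_se <- 1 / sqrt(2 * n_exposure * ns_maf * (1 - ns_maf))
  ns_beta <- 3.5 * ns_se * sample(c(-1, 1), 10, replace = TRUE)
  ns_tbl <- tibble::tibble(
    rsid = ns_rsid, chrom = as.character(rep(1:10)),
    pos = as.integer(1.5e8 + (1:10) * 1e6),
    effect_allele = "A", other_allele = "G",
    beta = ns_beta, se = ns_se,
    pval = 2 * pnorm(-abs(ns_beta / ns_se)),
    eaf = ns_maf, n = n_exposure
  )

  exposure <- as_summary_stats(
    dplyr::bind_rows(index_tbl, sat_tbl, ns_tbl),
    trait_label = "exposure (SD units)", n_total = n_exposure
  )

  # ---- outcome table ------------------------------------------------------
  # representation of each directly-shared region in the outcome study
  direct <- setdiff(seq_len(n_region), c(proxied, unproxied))
  rows <- vector("list", n_region)
  rep_cycle <- c("direct", "swap", "complement", "complement_swap")
  for (i in direct) {
    b1 <- ea[i]; b2 <- oa[i]; by <- beta_y[i]; ey <- eaf_y[i]
    if (i %in% pal_regions) {
      if (i == 9L) { # labels swapped; frequency inference must undo it
        tmp <- b1; b1 <- b2; b2 <- tmp
        by <- -by; ey <- 1 - ey
      }
      if (i == 10L) { # reported on the opposite orientation outright
        by <- -by; ey <- 1 - ey
      }
    } else if (i == incompat) {
      b2 <- setdiff(c("A", "C", "G", "T"), c(b1, b2, flip_strand(b1)))[1]
    } else {
      mode <- rep_cycle[(i %% 4) + 1]
      if (mode %in% c("swap", "complement_swap")) {
        tmp <- b1; b1 <- b2; b2 <- tmp
        by <- -by; ey <- 1 - ey
      }
      if (mode %in% c("complement", "complement_swap")) {
        b1 <- flip_strand(b1); b2 <- flip_strand(b2)
      }
    }
    rows[[i]] <- tibble::tibble(
      rsid = rsid[i], chrom = chrom[i], pos = pos[i],
      effect_allele = b1, other_allele = b2,
      beta = by, se = se_y[i],
      pval = pmax(2 * pnorm(-abs(by / se_y[i])), 1e-300),
      eaf = ey, n = n_case + n_control
    )
  }
  outcome_main <- dplyr::bind_rows(rows)

  # satellites are measured in the outcome too (direct representation)
  sat_beta_y <- rnorm(length(sat_region),
                      sat_r * Gamma_true[sat_region], se_y[sat_region])
  sat_out <- tibble::tibble(
    rsid = sat_rsid, chrom = chrom[sat_region],
    pos = pos[sat_region] + 30000L,
    effect_allele = ea[sat_region], other_allele = oa[sat_region],
    beta = sat_beta_y, se = se_y[sat_region],
    pval = pmax(2 * pnorm(-abs(sat_beta_y / se_y[sat_region])), 1e-300),
    eaf = pmin(pmax(eaf[sat_region] + rnorm(length(sat_region), 0, 0.008),
                    0.02), 0.98),
    n = n_case + n_control
  )

  # proxy SNPs measured in the outcome (targets rs1049/rs1050 are not);
  # rs2003 is only weakly linked to rs1051 and must be rejected
  proxy_rsid <- c("rs2001", "rs2002", "rs2003")
  proxy_of <- c(49L, 50L, 51L)
  proxy_phase <- c(1, -1, 1)
  proxy_ld <- c(0.97, 0.97, 0.40)
  proxy_beta <- rnorm(3, proxy_phase * proxy_ld * Gamma_true[proxy_of],
                      se_y[proxy_of])
  proxy_ea <- ifelse(proxy_phase > 0, ea[proxy_of], oa[proxy_of])
  proxy_oa <- ifelse(proxy_phase > 0, oa[proxy_of], ea[proxy_of])
  proxy_eaf <- ifelse(proxy_phase > 0, eaf[proxy_of], 1 - eaf[proxy_of])
  proxy_out <- tibble::tibble(
    rsid = proxy_rsid, chrom = chrom[proxy_of],
    pos = pos[proxy_of] + 5000L,
    effect_allele = proxy_ea, other_allele = proxy_oa,
    beta = proxy_beta, se = se_y[proxy_of],
    pval = pmax(2 * pnorm(-abs(proxy_beta / se_y[proxy_of])), 1e-300),
    eaf = pmin(pmax(proxy_eaf + rnorm(3, 0, 0.008), 0.02), 0.98),
    n = n_case + n_control
  )

  outcome <- as_summary_stats(
    dplyr::bind_rows(outcome_main, sat_out, proxy_out),
    trait_label = "outcome (log-odds)", n_total = n_case + n_control
  )

  # ---- reference panel ----------------------------------------------------
  n_ref <- 600L
  all_rsid <- c(rsid, sat_rsid, proxy_rsid)
  geno <- matrix(0, nrow = n_ref, ncol = length(all_rsid),
                 dimnames = list(NULL, all_rsid))
  for (i in seq_len(n_region)) {
    geno[, rsid[i]] <- rbinom(n_ref, 2, eaf[i])
  }
  resample <- function(base, frac, p) {
    d <- base
    k <- max(1L, round(frac * n_ref))
    sel <- sample.int(n_ref, k)
    d[sel] <- rbinom(k, 2, p)
    d
  }
  for (s in seq_along(sat_region)) {
    i <- sat_region[s]
    geno[, sat_rsid[s]] <- resample(geno[, rsid[i]], 0.06, eaf[i])
  }
  geno[, "rs2001"] <- resample(geno[, rsid[49]], 0.03, eaf[49])
  geno[, "rs2002"] <- 2 - resample(geno[, rsid[50]], 0.03, eaf[50])
  geno[, "rs2003"] <- resample(geno[, rsid[51]], 0.60, eaf[51])

  info <- tibble::tibble(
    rsid = all_rsid,
    chrom = c(chrom, chrom[sat_region], chrom[proxy_of]),
    pos = c(pos, pos[sat_region] + 30000L, pos[proxy_of] + 5000L),
    counted_allele = c(ea, ea[sat_region], proxy_ea)
  )
  panel <- ld_panel(genotypes = geno, info = info)

  # ---- trait-category annotations ----------------------------------------
  kept_regions <- setdiff(seq_len(n_region), c(ambiguous, incompat, unproxied))
  cats <- c(rep("lipid", 12), rep("blood", 10), rep("inflammation", 6),
            rep("body_composition", 5), rep("type_2_diabetes", 4),
            rep("other", length(kept_regions) - 37))
  region_cat <- stats::setNames(cats, kept_regions)
  annotations <- tibble::tibble(rsid = rsid[kept_regions], category = cats)
  # satellites share their region's annotation (a clump may be indexed by
  # either member), and outlier instruments carry secondary blood
  # associations as well
  annotations <- dplyr::distinct(dplyr::bind_rows(
    annotations,
    tibble::tibble(rsid = sat_rsid,
                   category = unname(region_cat[as.character(sat_region)])),
    tibble::tibble(rsid = rsid[outlier_regions], category = "blood")
  ))

  truth <- tibble::tibble(
    rsid = rsid, gamma = gam, delta = delta,
    valid = delta == 0, maf = maf
  )
  attr(truth, "theta") <- theta

  structure(list(
    exposure = exposure, outcome = outcome, panel = panel,
    annotations = annotations, truth = truth,
    params = list(n_snp = nrow(exposure), n_exposure = n_exposure,
                  n_case = n_case, n_control = n_control,
                  theta = theta, seed = seed)
  ), class = "mr_simulation")
}
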