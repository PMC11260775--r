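# Synthetic two-sample GWAS summary statistics with known causal truth.
#
# The generator instantiates the standard instrumental-variable diagram:
# instruments affect the exposure with effects gamma_j (SD units); the
# exposure affects the binary outcome with causal log-odds theta per SD;
# invalid instruments additionally carry a direct (pleiotropic) effect
# delta_j on the outcome. Summary statistics are drawn from the normal
# sampling model implied by the study sample sizes.

#' Simulate a two-sample MR study
#'
#' Generates exposure and outcome summary-statistic tables, an optional
#' genotype reference panel realizing the requested LD blocks, and the
#' generating truth. Per SNP j: MAF `x_j ~ U(maf_range)`; instrument
#' effect `gamma_j ~ N(0, gamma_sd^2)` truncated away from zero at
#' `gamma_min`; exposure SE `1/sqrt(2 n_exposure x_j (1 - x_j))` (SD-unit
#' trait); outcome SE `1/sqrt(2 v x_j (1 - x_j))` with effective size
#' `v = n_case n_control / (n_case + n_control)` (binary-trait
#' approximation); observed effects drawn from normals centred on the
#' truth, with true outcome effect `theta * gamma_j + delta_j`. A
#' `fraction_invalid` of instruments receives `delta_j ~ N(pleiotropy_mean,
#' pleiotropy_sd^2)` (`balanced = TRUE` forces the mean to zero).
#' Requested fractions of palindromic allele pairs and of strand-recoded
#' outcome records are injected so the harmonization stage is exercised.
#' Everything is reproducible from `seed`.
#'
#' @param n_snp Number of candidate instruments.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_case,n_control Outcome study case/control counts.
#' @param theta True causal log-odds of the outcome per 1 SD exposure.
#' @param maf_range Range of the uniform MAF law.
#' @param gamma_sd,gamma_min Scale and truncation of instrument effects.
#' @param fraction_invalid Fraction of instruments with pleiotropy.
#' @param pleiotropy_mean,pleiotropy_sd Normal law of the direct effects.
#' @param balanced Force mean-zero (balanced) pleiotropy.
#' @param ld_block_size SNPs per LD block (1 = independent SNPs); blocks
#'   beyond the first member are correlated satellites of the block index.
#' @param ld_r Target dosage correlation within a block.
#' @param n_ref Reference-panel individuals.
#' @param palindromic_fraction Fraction of SNPs given A/T or C/G alleles.
#' @param strand_flip_fraction Fraction of non-palindromic outcome records
#'   reported on the complementary strand.
#' @param invalid_category Optional trait-category label; when set, an
#'   annotation table is generated tagging the invalid instruments with it
#'   (valid instruments are tagged `"other"`).
#' @param include_panel Generate the genotype panel (disable for speed in
#'   summary-only simulations).
#' @param seed Integer seed (required).
#' @return Object of class `mr_simulation`: list with `exposure`,
#'   `outcome` (validated summary tables), `panel` (or `NULL`),
#'   `annotations` (or `NULL`) and `truth` (tibble `rsid`, `gamma`,
#'   `delta`, `valid`; attribute `theta`).
#' @export
simulate_mr_study <- function(n_snp = 50,
                              n_exposure = 114999,
                              n_case = 9358, n_control = 15482,
                              theta = 0,
                              maf_range = c(0.05, 0.5),
                              gamma_sd = 0.08, gamma_min = 0.02,
                              fraction_invalid = 0,
                              pleiotropy_mean = 0, pleiotropy_sd = 0.05,
                              balanced = FALSE,
                              ld_block_size = 1, ld_r = 0.95, n_ref = 500,
                              palindromic_fraction = 0.15,
                              strand_flip_fraction = 0.1,
                              invalid_category = NULL,
                              include_panel = TRUE,
                              seed = NULL) {
  if (is.null(seed)) stop_config("a `seed` is required")
  check_number(n_snp, "n_snp", 1)
  check_number(fraction_invalid, "fraction_invalid", 0, 1, open_upper = TRUE)
  check_number(palindromic_fraction, "palindromic_fraction", 0, 1)
  check_number(strand_flip_fraction, "strand_flip_fraction", 0, 1)
  check_number(ld_block_size, "ld_block_size", 1)
  check_number(ld_r, "ld_r", 0, 1)
  if (ld_block_size > 1 && ld_r <= sqrt(0.001)) {
    stop_config("within-block LD target too low to form blocks")
  }
  withr::local_seed(as.integer(seed))
  if (balanced) pleiotropy_mean <- 0

  n_blocks <- ceiling(n_snp / ld_block_size)
  block <- rep(seq_len(n_blocks), each = ld_block_size)[seq_len(n_snp)]
  within <- stats::ave(seq_len(n_snp), block, FUN = seq_along)
  is_index <- within == 1

  rsid <- sprintf("rs%06d", seq_len(n_snp))
  chrom <- as.character(((block - 1) %% 22) + 1)
  region <- ((block - 1) %/% 22)
  # block spacing: generously beyond the clumping window where the
  # chromosome can afford it, shrinking only for very large SNP counts
  per_chrom <- max(1, ceiling(n_blocks / 22))
  spacing <- max(1e5, min(3e7, floor(1.9e9 / per_chrom)))
  pos <- as.integer(2e7 + region * spacing + (within - 1) * 2e4)

  x <- runif(n_snp, maf_range[1], maf_range[2])
  # truncated-normal instrument effects, sign-symmetric
  gam <- numeric(n_snp)
  todo <- rep(TRUE, n_snp)
  while (any(todo)) {
    draw <- rnorm(sum(todo), 0, gamma_sd)
    ok <- abs(draw) >= gamma_min
    gam[todo][ok] <- draw[ok]
    todo[todo] <- !ok
  }
  # satellites inherit an attenuated copy of their block index effect
  if (ld_block_size > 1) {
    gam <- ifelse(is_index, gam, ld_r * gam[which(is_index)[block]])
  }

  n_invalid <- round(fraction_invalid * n_snp)
  invalid <- rep(FALSE, n_snp)
  if (n_invalid > 0) invalid[sample.int(n_snp, n_invalid)] <- TRUE
  delta <- ifelse(invalid, rnorm(n_snp, pleiotropy_mean, pleiotropy_sd), 0)

  se_x <- 1 / sqrt(2 * n_exposure * x * (1 - x))
  v_eff <- n_case * n_control / (n_case + n_control)
  se_y <- 1 / sqrt(2 * v_eff * x * (1 - x))
  beta_x <- rnorm(n_snp, gam, se_x)
  # pleiotropic effects are expressed in the orientation of the
  # exposure-increasing allele, so a non-zero mean is genuinely
  # directional rather than cancelling across arbitrary allele codings
  beta_y <- rnorm(n_snp, theta * gam + sign(gam) * delta, se_y)

  # allele assignment
  palin <- runif(n_snp) < palindromic_fraction
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  np_pairs <- list(c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
                   c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T"))
  pair_idx <- ifelse(palin, sample.int(4, n_snp, replace = TRUE),
                     sample.int(8, n_snp, replace = TRUE))
  ea <- oa <- character(n_snp)
  for (i in seq_len(n_snp)) {
    p <- if (palin[i]) pal_pairs[[pair_idx[i]]] else np_pairs[[pair_idx[i]]]
    ea[i] <- p[1]
    oa[i] <- p[2]
  }
  # effect allele frequency: effect allele is the minor or major one at random
  minor_is_effect <- runif(n_snp) < 0.5
  eaf <- ifelse(minor_is_effect, x, 1 - x)
  eaf_y <- pmin(pmax(eaf + rnorm(n_snp, 0, 0.005), 0.001), 0.999)

  exposure <- as_summary_stats(tibble::tibble(
    rsid = rsid, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa,
    beta = beta_x, se = se_x,
    pval = pmax(2 * pnorm(-abs(beta_x / se_x)), 1e-300),
    eaf = eaf, n = as.integer(n_exposure)
  ), trait_label = "simulated exposure", n_total = n_exposure)

  # outcome records: some reported swapped and/or on the complement strand
  ea_y <- ea; oa_y <- oa; b_y <- beta_y; e_y <- eaf_y
  swap <- runif(n_snp) < 0.3
  ea_y[swap] <- oa[swap]; oa_y[swap] <- ea[swap]
  b_y[swap] <- -b_y[swap]; e_y[swap] <- 1 - e_y[swap]
  flip <- !palin & (runif(n_snp) < strand_flip_fraction)
  ea_y[flip] <- flip_strand(ea_y[flip])
  oa_y[flip] <- flip_strand(oa_y[flip])

  outcome <- as_summary_stats(tibble::tibble(
    rsid = rsid, chrom = chrom, pos = pos,
    effect_allele = ea_y, other_allele = oa_y,
    beta = b_y, se = se_y,
    pval = pmax(2 * pnorm(-abs(b_y / se_y)), 1e-300),
    eaf = e_y, n = as.integer(n_case + n_control)
  ), trait_label = "simulated outcome", n_total = n_case + n_control)

  panel <- NULL
  if (include_panel) {
    geno <- matrix(0, nrow = n_ref, ncol = n_snp,
                   dimnames = list(NULL, rsid))
    for (b in seq_len(n_blocks)) {
      members <- which(block == b)
      lead <- members[1]
      geno[, lead] <- rbinom(n_ref, 2, x[lead])
      for (m in members[-1]) {
        # correlated satellite: copy the index, resample a fraction
        d <- geno[, lead]
        n_swap <- max(1, round((1 - ld_r) * n_ref))
        sel <- sample.int(n_ref, n_swap)
        d[sel] <- rbinom(n_swap, 2, x[lead])
        geno[, m] <- d
      }
    }
    counted <- ifelse(minor_is_effect, ea, oa) # panel counts the minor allele
    panel <- ld_panel(genotypes = geno, info = tibble::tibble(
      rsid = rsid, chrom = chrom, pos = pos, counted_allele = counted))
  }

  annotations <- NULL
  if (!is.null(invalid_category)) {
    annotations <- tibble::tibble(
      rsid = rsid,
      category = ifelse(invalid, invalid_category, "other")
    )
  }

  truth <- tibble::tibble(rsid = rsid, gamma = gam, delta = delta,
                          valid = !invalid, maf = x)
  attr(truth, "theta") <- theta

  structure(list(
    exposure = exposure, outcome = outcome, panel = panel,
    annotations = annotations, truth = truth,
    params = list(n_snp = n_snp, n_exposure = n_exposure, n_case = n_case,
                  n_control = n_control, theta = theta, seed = seed)
  ), class = "mr_simulation")
}

#' @export
print.mr_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulated two-sample MR study: %d SNPs, theta = %.3f, seed = %d\n",
    x$params$n_snp, x$params$theta, x$params$seed))
  invisible(x)
}

#' Harmonized instrument set straight from a simulation's truth alignment
#'
#' Convenience for estimator validation: pairs the simulated exposure and
#' outcome records on the generating (exposure) allele orientation without
#' running allele harmonization, so no instruments are lost to palindromic
#' ambiguity. Uses the generator's knowledge that both tables were
#' produced on a common true orientation.
#'
#' @param sim An `mr_simulation`.
#' @return Harmonized-format tibble usable by the estimators.
#' @export
simulated_instruments <- function(sim) {
  ex <- sim$exposure
  tr <- sim$truth
  i <- match(ex$rsid, tr$rsid)
  # reconstruct the outcome effect on the exposure orientation
  ou <- sim$outcome
  j <- match(ex$rsid, ou$rsid)
  pal <- is_palindromic_pair(ex$effect_allele, ex$other_allele)
  # palindromic labels are strand-invariant (the generator injects no
  # strand recoding for them), so only a direct label match counts there
  same <- ifelse(
    pal,
    ou$effect_allele[j] == ex$effect_allele,
    ou$effect_allele[j] == ex$effect_allele |
      flip_strand(ou$effect_allele[j]) == ex$effect_allele
  )
  tibble::tibble(
    rsid = ex$rsid, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_exposure = ex$beta, se_exposure = ex$se, eaf_exposure = ex$eaf,
    pval_exposure = ex$pval,
    beta_outcome = ifelse(same, ou$beta[j], -ou$beta[j]),
    se_outcome = ou$se[j],
    eaf_outcome = ifelse(same, ou$eaf[j], 1 - ou$eaf[j]),
    pval_outcome = ou$pval[j],
    is_proxy = FALSE, proxy_rsid = NA_character_, action = "kept",
    gamma_true = tr$gamma[i], delta_true = tr$delta[i], valid = tr$valid[i]
  )
}
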