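# allele harmonization and instrument strength

ex_row <- function(rsid, ea, oa, beta, eaf, se = 0.01, pval = 1e-10) {
  tibble::tibble(rsid = rsid, chrom = "1",
                 pos = 1000L * (1L + as.integer(factor(rsid))),
                 effect_allele = ea, other_allele = oa,
                 beta = beta, se = se, pval = pval, eaf = eaf,
                 n = NA_integer_)
}

test_that("swapped outcome alleles are flipped with frequency symmetry", {
  ex <- suppressWarnings(as_summary_stats(ex_row("rs1", "A", "G", 0.10, 0.20)))
  ou <- suppressWarnings(as_summary_stats(ex_row("rs1", "G", "A", -0.05, 0.80)))
  h <- harmonize(ex, ou)
  expect_equal(nrow(h), 1)
  expect_equal(h$beta_outcome, 0.05)
  expect_equal(h$eaf_outcome, 0.20)
  expect_equal(h$action, "flipped")
  expect_equal(h$effect_allele, "A") # exposure orientation untouched
})

test_that("strand-complemented records are recognized, with and without swap", {
  ex <- suppressWarnings(as_summary_stats(ex_row("rs1", "A", "G", 0.10, 0.20)))
  comp <- suppressWarnings(as_summary_stats(ex_row("rs1", "T", "C", 0.07, 0.21)))
  h <- harmonize(ex, comp)
  expect_equal(h$action, "strand_complemented")
  expect_equal(h$beta_outcome, 0.07)

  comp_swap <- suppressWarnings(as_summary_stats(
    ex_row("rs1", "C", "T", 0.07, 0.79)))
  h2 <- harmonize(ex, comp_swap)
  expect_equal(h2$action, "strand_complemented_flipped")
  expect_equal(h2$beta_outcome, -0.07)
  expect_equal(h2$eaf_outcome, 0.21)
})

test_that("palindromic SNPs are inferred below the MAF threshold, else dropped", {
  # low MAF, concordant frequencies: orientation inferable
  ex <- suppressWarnings(as_summary_stats(ex_row("rs1", "A", "T", 0.10, 0.10)))
  ou <- suppressWarnings(as_summary_stats(ex_row("rs1", "A", "T", 0.04, 0.12)))
  h <- harmonize(ex, ou)
  expect_equal(h$action, "palindromic_inferred")
  expect_equal(h$beta_outcome, 0.04)

  # discordant frequencies at low MAF: the flip is inferred
  ou2 <- suppressWarnings(as_summary_stats(ex_row("rs1", "A", "T", 0.04, 0.88)))
  h2 <- harmonize(ex, ou2)
  expect_equal(h2$action, "palindromic_inferred_flipped")
  expect_equal(h2$beta_outcome, -0.04)
  expect_equal(h2$eaf_outcome, 0.12)

  # MAF at or above 0.3 in either study: ambiguous, dropped
  ex3 <- suppressWarnings(as_summary_stats(ex_row("rs1", "C", "G", 0.10, 0.45)))
  ou3 <- suppressWarnings(as_summary_stats(ex_row("rs1", "C", "G", 0.04, 0.44)))
  h3 <- harmonize(ex3, ou3)
  expect_equal(nrow(h3), 0)
  aud <- harmonization_audit(h3)
  expect_equal(aud$reason, "palindromic_ambiguous")

  # palindromic without frequencies cannot be oriented at all
  ex4 <- ex_row("rs1", "A", "T", 0.10, NA)
  ou4 <- ex_row("rs1", "A", "T", 0.04, 0.12)
  h4 <- harmonize(ex4, ou4)
  expect_equal(harmonization_audit(h4)$reason, "palindromic_no_eaf")
})

test_that("irreconcilable allele sets are dropped as incompatible", {
  ex <- suppressWarnings(as_summary_stats(ex_row("rs1", "A", "G", 0.10, 0.20)))
  ou <- suppressWarnings(as_summary_stats(ex_row("rs1", "A", "C", 0.05, 0.20)))
  h <- harmonize(ex, ou)
  expect_equal(nrow(h), 0)
  expect_equal(harmonization_audit(h)$reason, "incompatible_alleles")
})

test_that("harmonization is involution-safe and orientation-invariant", {
  sim <- simulate_mr_study(n_snp = 40, palindromic_fraction = 0.2,
                           strand_flip_fraction = 0.2, include_panel = FALSE,
                           seed = 88)
  h1 <- harmonize(sim$exposure, sim$outcome)
  expect_gt(nrow(h1), 0)

  # re-harmonizing the harmonized pairs changes nothing
  as_ex <- h1[c("rsid", "chrom", "pos", "effect_allele", "other_allele")]
  as_ex$beta <- h1$beta_exposure; as_ex$se <- h1$se_exposure
  as_ex$pval <- h1$pval_exposure; as_ex$eaf <- h1$eaf_exposure
  as_ou <- h1[c("rsid", "chrom", "pos", "effect_allele", "other_allele")]
  as_ou$beta <- h1$beta_outcome; as_ou$se <- h1$se_outcome
  as_ou$pval <- h1$pval_outcome; as_ou$eaf <- h1$eaf_outcome
  h2 <- harmonize(suppressWarnings(as_summary_stats(as_ex)),
                  suppressWarnings(as_summary_stats(as_ou)))
  expect_equal(sort(h2$rsid), sort(h1$rsid))
  m <- match(h1$rsid, h2$rsid)
  expect_equal(h2$beta_outcome[m], h1$beta_outcome)
  expect_equal(h2$beta_exposure[m], h1$beta_exposure)

  # flipping every outcome record's orientation leaves the result identical
  ou_flip <- sim$outcome
  tmp <- ou_flip$effect_allele
  ou_flip$effect_allele <- ou_flip$other_allele
  ou_flip$other_allele <- tmp
  ou_flip$beta <- -ou_flip$beta
  ou_flip$eaf <- 1 - ou_flip$eaf
  h3 <- harmonize(sim$exposure, ou_flip)
  expect_equal(sort(h3$rsid), sort(h1$rsid))
  m <- match(h1$rsid, h3$rsid)
  expect_equal(h3$beta_outcome[m], h1$beta_outcome)
  expect_equal(h3$eaf_outcome[m], h1$eaf_outcome)
})

test_that("the audit conserves every input SNP across kept and dropped", {
  for (seed in c(11, 12, 13)) {
    sim <- simulate_mr_study(n_snp = 30, palindromic_fraction = 0.3,
                             strand_flip_fraction = 0.2,
                             include_panel = FALSE, seed = seed)
    h <- harmonize(sim$exposure, sim$outcome)
    aud <- harmonization_audit(h)
    expect_equal(nrow(aud), nrow(sim$exposure))
    expect_equal(sum(aud$action == "kept"), nrow(h))
    expect_setequal(aud$rsid, sim$exposure$rsid)
  }
})

test_that("variance explained and the F-statistic follow the stated formulas", {
  rec <- ex_row("rs1", "A", "G", 0.5, 0.1)
  st <- instrument_strength(rec, n = 1000)
  expect_equal(st$r2_total, 2 * 0.25 * 0.1 * 0.9) # 0.045
  expect_equal(instrument_strength(rec, n = 1000,
                                   formula = "as_printed")$r2_total,
               0.25 * 0.1 * 0.9)

  zero <- ex_row("rs1", "A", "G", 0, 0.1)
  st0 <- instrument_strength(zero, n = 1000)
  expect_equal(st0$r2_total, 0)
  expect_equal(st0$f_statistic, 0)

  # published-scale inputs: R2 = 10.2%, n = 114,999, k = 42
  f <- mr_f_statistic(0.102, 114999, 42)
  expect_equal(f, (0.102 / 42) / ((1 - 0.102) / (114999 - 43)))
  expect_equal(f, 310.9, tolerance = 1e-3)

  # MAF is used, not the raw effect-allele frequency
  high <- ex_row("rs1", "A", "G", 0.5, 0.9)
  expect_equal(instrument_strength(high, n = 1000)$r2_total, 0.045)

  miss <- ex_row("rs1", "A", "G", 0.5, NA)
  expect_error(instrument_strength(miss, n = 1000), "rs1",
               class = "mrkit_data_error")
})
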