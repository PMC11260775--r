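# shared builders for the test suite

# a minimal harmonized instrument table from effect vectors
h_set <- function(gamma, Gamma, se_x = 1e-3, se_y = 0.1,
                  rsid = sprintf("rs%03d", seq_along(gamma))) {
  n <- length(gamma)
  tibble::tibble(
    rsid = rsid,
    chrom = "1", pos = seq_len(n) * 1000L,
    effect_allele = "A", other_allele = "G",
    beta_exposure = gamma, se_exposure = rep_len(se_x, n),
    eaf_exposure = 0.2, pval_exposure = 1e-10,
    beta_outcome = Gamma, se_outcome = rep_len(se_y, n),
    eaf_outcome = 0.2, pval_outcome = 0.5,
    is_proxy = FALSE, proxy_rsid = NA_character_, action = "kept"
  )
}

# a harmonized table whose ratio estimates and weights are exactly as given:
# gamma_j = sqrt(w_j) * se_y, Gamma_j = theta_j * gamma_j
ratio_set <- function(theta, w = rep(1, length(theta)), se_y = 0.1) {
  gamma <- sqrt(w) * se_y
  h_set(gamma, theta * gamma, se_y = se_y)
}

# a valid raw summary-statistics data frame
raw_sumstats <- function(n = 3) {
  tibble::tibble(
    rsid = sprintf("rs%d", seq_len(n)),
    chrom = "1", pos = seq_len(n) * 100000L,
    effect_allele = rep_len(c("A", "C", "G"), n),
    other_allele = rep_len(c("G", "T", "A"), n),
    beta = seq_len(n) / 100, se = 0.01, pval = 1e-9,
    eaf = 0.25, n = 10000L
  )
}

# summary-level simulation without allele/LD complications, for estimator
# checks on the true orientation
sim_instruments <- function(..., seed) {
  simulated_instruments(simulate_mr_study(
    ..., palindromic_fraction = 0, strand_flip_fraction = 0,
    include_panel = FALSE, seed = seed))
}
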