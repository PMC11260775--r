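# heterogeneity, pleiotropy, outlier and category-exclusion analyses

test_that("Cochran's Q matches the hand-evaluated example and its bounds", {
  d <- h_set(gamma = c(0.1, 0.2), Gamma = c(0.2, 0.2), se_y = 0.1)
  q <- mr_cochran_q(d)
  # Q = 1*(2 - 1.2)^2 + 4*(1 - 1.2)^2 = 0.8 with df = 1
  expect_equal(q$q_stat, 0.8, tolerance = 1e-12)
  expect_equal(q$q_df, 1L)
  # chi-square(1) tail evaluated through the normal closed form
  expect_equal(q$q_pval, 2 * pnorm(-sqrt(0.8)), tolerance = 1e-12)

  # Q = 0 (p = 1) exactly when all ratios coincide
  same <- ratio_set(c(1.3, 1.3, 1.3, 1.3))
  q0 <- mr_cochran_q(same)
  expect_equal(q0$q_stat, 0)
  expect_equal(q0$q_pval, 1)

  # Q >= 0 and positive whenever ratios differ
  for (seed in 1:5) {
    dat <- sim_instruments(n_snp = 10, theta = 0.1, seed = seed)
    expect_gte(mr_cochran_q(dat)$q_stat, 0)
    expect_gt(mr_cochran_q(dat)$q_stat, 0)
  }
  expect_error(mr_cochran_q(ratio_set(1)), class = "mrkit_data_error")
})

test_that("the Egger intercept test reads off the egger fit", {
  g <- c(0.1, 0.2, 0.3, 0.4)
  d <- h_set(g, Gamma = 0.03 + 0.5 * g, se_y = 0.05)
  pt <- mr_pleiotropy_test(d)
  expect_equal(pt$egger_intercept, 0.03, tolerance = 1e-9)
})

test_that("MR-PRESSO flags a planted outlier and reports no distortion when
           removal changes nothing", {
  dat <- sim_instruments(n_snp = 50, theta = 0.1, seed = 1201)
  bad <- 17
  dat$beta_outcome[bad] <- dat$beta_outcome[bad] + 10 * dat$se_outcome[bad]
  pr <- mr_presso(dat, n_sim = 1000, seed = 3)
  expect_true(dat$rsid[bad] %in% pr$outlier_rsids)
  expect_lt(pr$global_pval, 0.05)
  expect_true(pr$distortion_defined)
  expect_equal(pr$beta_no_outliers,
               mr_ivw(dat[-match(pr$outlier_rsids, dat$rsid), ])$b)

  # clean data: global test quiet, zero distortion by definition
  clean <- sim_instruments(n_snp = 50, theta = 0.1, seed = 1202)
  pr0 <- mr_presso(clean, n_sim = 500, seed = 4)
  expect_gt(pr0$global_pval, 0.05)
  expect_equal(length(pr0$outlier_rsids), 0)
  expect_equal(pr0$distortion_coefficient, 0)
  expect_equal(pr0$beta_no_outliers, pr0$beta_all)

  expect_error(mr_presso(clean[1:3, ], n_sim = 100, seed = 1),
               class = "mrkit_data_error")
  expect_error(mr_presso(clean, n_sim = 100), class = "mrkit_config_error")
})

test_that("MR-PRESSO is reproducible from its seed", {
  dat <- sim_instruments(n_snp = 20, theta = 0, seed = 77)
  p1 <- mr_presso(dat, n_sim = 200, seed = 9)
  p2 <- mr_presso(dat, n_sim = 200, seed = 9)
  expect_equal(p1$global_pval, p2$global_pval)
  expect_equal(p1$outliers$pval, p2$outliers$pval)
})

test_that("leave-one-out is complete, stable for homogeneous sets, and
           isolates a planted outlier", {
  dat3 <- sim_instruments(n_snp = 3, theta = 0.2, seed = 5)
  expect_equal(nrow(mr_leave_one_out(dat3)), 3)

  dat <- sim_instruments(n_snp = 40, theta = 0.2, seed = 6)
  full <- mr_ivw(dat)
  loo <- mr_leave_one_out(dat)
  se_fixed <- mr_ivw(dat, model = "fixed")$se
  expect_true(all(abs(loo$beta - full$b) < se_fixed))

  # removing the sole outlier moves the estimate toward the truth
  spiked <- dat
  spiked$beta_outcome[1] <- spiked$beta_outcome[1] + 12 * spiked$se_outcome[1]
  loo2 <- mr_leave_one_out(spiked)
  biased <- mr_ivw(spiked)$b
  without <- loo2$beta[loo2$rsid == spiked$rsid[1]]
  expect_lt(abs(without - 0.2), abs(biased - 0.2))
})

test_that("category exclusion mirrors the main analysis code path", {
  dat <- sim_instruments(n_snp = 20, theta = 0.1, seed = 31)
  ann <- tibble::tibble(rsid = dat$rsid[1:5], category = "lipid")

  # a category annotating no instruments reproduces the main analysis
  none <- tibble::tibble(rsid = "rs_unrelated", category = "blood")
  main <- mr_all_methods(dat, n_boot = 50, seed = 11)
  res <- mr_category_exclusion(dat, none, categories = "blood",
                               n_boot = 50, seed = 11)
  expect_equal(res$beta, main$beta)
  expect_equal(res$se, main$se)

  # excluding the annotated five drops them from the panel
  res2 <- mr_category_exclusion(dat, ann, categories = "lipid",
                                n_boot = 50, seed = 11)
  expect_true(all(res2$n_snp == 15))
  details <- attr(res2, "details")
  expect_false(any(dat$rsid[1:5] %in% details$lipid$snps))

  # keep-only restricts to the annotated five
  res3 <- mr_category_exclusion(dat, ann, categories = "lipid",
                                mode = "keep_only", n_boot = 50, seed = 11)
  expect_true(all(res3$n_snp == 5))

  # a category covering everything is recorded as not estimable
  all_ann <- tibble::tibble(rsid = dat$rsid, category = "blood")
  res4 <- mr_category_exclusion(dat, all_ann, categories = "blood",
                                n_boot = 50, seed = 11)
  expect_true(attr(res4, "details")$blood$not_estimable)
  expect_equal(res4$n_snp, 0L)
})

test_that("excluding a planted confounded category shrinks the Egger
           intercept toward zero", {
  withr::local_seed(4242)
  J <- 60
  # instrument strengths spanning toward zero keep the Egger intercept
  # well identified
  g <- runif(J, 0.02, 0.2)
  se_y <- rep(0.01, J)
  confounded <- seq_len(J) %in% sample(J, 20)
  delta <- ifelse(confounded, 0.15, 0) # directional pleiotropy in one category
  G <- 0.1 * g + delta + rnorm(J, 0, se_y)
  dat <- h_set(g, G, se_y = se_y)
  ann <- tibble::tibble(rsid = dat$rsid[confounded],
                        category = "inflammation")

  int_main <- mr_pleiotropy_test(dat)$egger_intercept
  res <- mr_category_exclusion(dat, ann, categories = "inflammation",
                               n_boot = 50, seed = 12)
  excl <- attr(res, "details")$inflammation$pleiotropy
  expect_lt(abs(excl$egger_intercept), abs(int_main))
  expect_lt(abs(excl$egger_intercept), 3 * excl$se)
})
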