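# the four causal estimators and their closed-form/simulation oracles

test_that("Wald ratios follow the delta-method closed form", {
  d <- h_set(gamma = 0.1, Gamma = 0.2, se_y = 0.05)
  w <- mr_wald_ratio(d)
  expect_equal(w$beta, 2.0)
  expect_equal(w$se, 0.5)

  expect_equal(mr_wald_ratio(h_set(1, 0))$beta, 0)
  expect_error(mr_wald_ratio(h_set(c(0.1, 0), c(0.1, 0.1))), "rs002",
               class = "mrkit_data_error")
})

test_that("IVW reproduces the hand-evaluated two-SNP example", {
  d <- h_set(gamma = c(0.1, 0.2), Gamma = c(0.2, 0.2), se_y = 0.1)
  fit <- mr_ivw(d)
  expect_equal(fit$b, 1.2, tolerance = 1e-12)
  expect_equal(fit$extras$q_stat, 0.8, tolerance = 1e-12)
  # Q/(J-1) < 1, so the random-effects SE equals the fixed-effect SE
  expect_equal(fit$se, 1 / sqrt(5), tolerance = 1e-12)
  expect_equal(mr_ivw(d, model = "fixed")$se, 1 / sqrt(5), tolerance = 1e-12)

  # oracle: the closed-form ratio of weighted sums
  w <- 1 / 0.1^2
  expect_equal(fit$b,
               (w * 0.1 * 0.2 + w * 0.2 * 0.2) / (w * 0.01 + w * 0.04))

  # a single SNP reduces exactly to the Wald ratio
  one <- h_set(0.1, 0.2, se_y = 0.05)
  expect_equal(mr_ivw(one)$b, mr_wald_ratio(one)$beta)
  expect_equal(mr_ivw(one)$se, mr_wald_ratio(one)$se)

  expect_error(mr_ivw(h_set(numeric(), numeric())),
               class = "mrkit_data_error")
})

test_that("IVW recovers the causal effect in a seeded simulation", {
  dat <- sim_instruments(n_snp = 50, theta = 0.3, seed = 301)
  fit <- mr_ivw(dat)
  expect_lt(abs(fit$b - 0.3), 3 * fit$se)
})

test_that("MR-Egger fits slope and intercept exactly on noise-free data", {
  g <- c(0.1, 0.2, 0.3)
  d <- h_set(g, Gamma = 0.05 + 2 * g, se_y = 0.1)
  fit <- mr_egger(d)
  expect_equal(fit$b, 2.0, tolerance = 1e-9)
  expect_equal(fit$extras$intercept, 0.05, tolerance = 1e-9)
  expect_equal(fit$extras$q_stat, 0, tolerance = 1e-12)

  # zero-intercept data
  d0 <- h_set(g, Gamma = 1.5 * g, se_y = 0.1)
  fit0 <- mr_egger(d0)
  expect_equal(fit0$extras$intercept, 0, tolerance = 1e-9)
  expect_equal(fit0$b, 1.5, tolerance = 1e-9)

  # identical instrument strengths leave the slope unidentified
  expect_warning(bad <- mr_egger(h_set(c(0.1, 0.1, 0.1), c(1, 2, 3))),
                 "identical")
  expect_true(bad$extras$collinear)
  expect_error(mr_egger(h_set(c(0.1, 0.2), c(1, 2))),
               class = "mrkit_data_error")
})

test_that("the Egger intercept recovers planted directional pleiotropy", {
  withr::local_seed(555)
  J <- 200
  g <- runif(J, 0.05, 0.2)
  se_y <- rep(0.02, J)
  delta <- rnorm(J, 0.02, 0.005) # directional pleiotropy, mean 0.02
  G <- 0.1 * g + delta + rnorm(J, 0, se_y)
  fit <- mr_egger(h_set(g, G, se_y = se_y))
  expect_lt(abs(fit$extras$intercept - 0.02),
            3 * fit$extras$intercept_se)
  expect_lt(abs(fit$b - 0.1), 3 * fit$se)
})

test_that("weighted median interpolates the cumulative-midpoint formula", {
  expect_equal(mrkit:::weighted_median_point(c(1, 2, 3), rep(1, 3)), 2.0)
  expect_equal(mrkit:::weighted_median_point(c(1, 2, 3, 10), c(3, 3, 3, 1)),
               2 + (0.5 - 0.45) / (0.75 - 0.45), tolerance = 1e-12)
  # order of the input must not matter
  expect_equal(mrkit:::weighted_median_point(c(10, 3, 1, 2), c(1, 3, 3, 3)),
               13 / 6, tolerance = 1e-12)

  d <- ratio_set(c(1, 2, 3))
  fit <- mr_weighted_median(d, n_boot = 200, seed = 1)
  expect_equal(fit$b, 2.0)
  expect_gt(fit$se, 0)
  expect_error(mr_weighted_median(d, n_boot = 1, seed = 1),
               class = "mrkit_config_error")
  expect_error(mr_weighted_median(d, n_boot = 100),
               class = "mrkit_config_error") # seed is mandatory
})

test_that("weighted median resists 40% invalid weight where IVW does not", {
  # strong instruments, true effect zero, large positive pleiotropy on 40%
  # of the weight: the weighted median stays within the single-SNP ratio
  # noise scale (its worst-case quantile shift) while IVW absorbs the
  # full directional bias
  withr::local_seed(777)
  J <- 100
  g <- runif(J, 0.08, 0.15)
  se_y <- rep(0.005, J)
  invalid <- sample(J, 40)
  delta <- numeric(J)
  delta[invalid] <- abs(rnorm(40, 0.1, 0.05))
  G <- 0 * g + delta + rnorm(J, 0, se_y)
  d <- h_set(g, G, se_y = se_y)

  med <- mr_weighted_median(d, n_boot = 200, seed = 2)
  ivw <- mr_ivw(d)
  expect_lt(abs(med$b), 0.08)       # at most the valid ratio-noise scale
  expect_gt(abs(ivw$b), 0.15)       # IVW demonstrably biased away
  expect_gt(abs(ivw$b), 2 * abs(med$b))
})

test_that("weighted mode finds the dominant ratio cluster", {
  d <- ratio_set(c(1.00, 1.01, 0.99, 5.0))
  fit <- mr_weighted_mode(d, n_boot = 100, seed = 3)
  expect_lt(abs(fit$b - 1.0), 0.02) # within a bandwidth of the cluster

  const <- ratio_set(c(1.7, 1.7, 1.7))
  expect_equal(mr_weighted_mode(const, n_boot = 50, seed = 4)$b, 1.7)

  # majority-invalid regime: 30 strong instruments carry ~60% of the
  # weight and are pleiotropic with heterogeneous two-sided offsets; the
  # largest homogeneous ratio cluster is the valid one at theta = 0.2
  withr::local_seed(888)
  g <- c(runif(30, 0.18, 0.25), runif(70, 0.08, 0.12))
  se_y <- rep(0.005, 100)
  delta <- c(sample(c(-1, 1), 30, TRUE) * runif(30, 0.15, 0.6), numeric(70))
  expect_gt(sum(g[1:30]^2) / sum(g^2), 0.5) # invalid majority of weight
  G <- 0.2 * g + delta + rnorm(100, 0, se_y)
  fit2 <- mr_weighted_mode(h_set(g, G, se_y = se_y), n_boot = 100, seed = 5)
  expect_lt(abs(fit2$b - 0.2), 3 * fit2$se)
  expect_lt(abs(fit2$b - 0.2), 0.05)
})

test_that("mr_all_methods reports estimates, single-SNP ratios and absences", {
  dat <- sim_instruments(n_snp = 42, theta = 0, seed = 99)
  est <- mr_all_methods(dat, n_boot = 50, seed = 6)
  expect_setequal(est$method,
                  c("ivw", "egger", "weighted_median", "weighted_mode"))
  expect_equal(nrow(attr(est, "singlesnp")), 42)
  expect_true(all(est$or == exp(est$beta)))
  expect_true(all(est$ci_low <= est$ci_high))

  one <- dat[1, ]
  est1 <- mr_all_methods(one, n_boot = 50, seed = 6)
  expect_equal(est1$method, "ivw") # single pair: only IVW (= Wald)
  absent <- attr(est1, "absent")
  expect_setequal(absent$method,
                  c("egger", "weighted_median", "weighted_mode"))
})

test_that("estimators are scale-equivariant and orientation-invariant", {
  dat <- sim_instruments(n_snp = 30, theta = 0.2, seed = 42)
  c_scale <- 3.7
  scaled <- dat
  scaled$beta_outcome <- dat$beta_outcome * c_scale
  scaled$se_outcome <- dat$se_outcome * c_scale

  for (f in list(mr_ivw, mr_egger)) {
    f0 <- f(dat); f1 <- f(scaled)
    expect_equal(f1$b, c_scale * f0$b, tolerance = 1e-9)
    expect_equal(f1$se, c_scale * f0$se, tolerance = 1e-9)
  }
  m0 <- mr_weighted_median(dat, n_boot = 100, seed = 7)
  m1 <- mr_weighted_median(scaled, n_boot = 100, seed = 7)
  expect_equal(m1$b, c_scale * m0$b, tolerance = 1e-9)
  expect_equal(m1$se, c_scale * m0$se, tolerance = 1e-9)

  # flipping the allele orientation of a subset of instruments
  flip <- seq_len(nrow(dat)) %% 3 == 0
  flipped <- dat
  flipped$beta_exposure[flip] <- -dat$beta_exposure[flip]
  flipped$beta_outcome[flip] <- -dat$beta_outcome[flip]
  expect_equal(mr_ivw(flipped)$b, mr_ivw(dat)$b, tolerance = 1e-12)
  expect_equal(mr_egger(flipped)$b, mr_egger(dat)$b, tolerance = 1e-9)
  expect_equal(mr_egger(flipped)$extras$intercept,
               mr_egger(dat)$extras$intercept, tolerance = 1e-9)
  expect_equal(mr_weighted_median(flipped, n_boot = 50, seed = 8)$b,
               mr_weighted_median(dat, n_boot = 50, seed = 8)$b,
               tolerance = 1e-12)
  expect_equal(mr_weighted_mode(flipped, n_boot = 50, seed = 8)$b,
               mr_weighted_mode(dat, n_boot = 50, seed = 8)$b,
               tolerance = 1e-9)
})

test_that("all four 95% CIs cover a null effect at close to nominal rate", {
  reps <- 300
  methods <- c("ivw", "egger", "weighted_median", "weighted_mode")
  cover <- matrix(0L, nrow = reps, ncol = 4, dimnames = list(NULL, methods))
  for (r in seq_len(reps)) {
    dat <- sim_instruments(n_snp = 30, theta = 0, seed = 20000 + r)
    est <- mr_all_methods(dat, n_boot = 60, seed = 30000 + r)
    m <- match(methods, est$method)
    cover[r, ] <- as.integer(est$ci_low[m] <= 0 & 0 <= est$ci_high[m])
  }
  expect_true(all(colMeans(cover) >= 0.93))
})
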