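# Causal-effect estimators on a harmonized instrument set.
#
# Notation: per SNP j, gamma_j / se_x,j are the exposure association and its
# SE (SD units of the exposure), Gamma_j / se_y,j the outcome association
# and its SE (log-odds units). All estimators target the causal log-odds of
# the outcome per 1 SD increase in the exposure.

new_mr_fit <- function(method, nsnp, b, se, pval, extras = list()) {
  z <- Z95()
  structure(list(
    method = method, nsnp = nsnp, b = b, se = se,
    ci_low = b - z * se, ci_high = b + z * se, pval = pval,
    or_ = exp(b), or_ci_low = exp(b - z * se), or_ci_high = exp(b + z * se),
    extras = extras
  ), class = "mr_fit")
}

#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_snp = x$nsnp, beta = x$b, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
    or = x$or_, or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high
  )
}

#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  out <- tibble::tibble(method = x$method, n_snp = x$nsnp)
  for (nm in names(x$extras)) {
    v <- x$extras[[nm]]
    if (is.numeric(v) && length(v) == 1) out[[nm]] <- v
  }
  out
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf(
    "%s (%d SNPs): beta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
    x$method, x$nsnp, x$b, x$se, x$or_, x$or_ci_low, x$or_ci_high, x$pval))
  invisible(x)
}

ratio_stats <- function(dat) {
  g <- dat$beta_exposure
  if (any(g == 0)) {
    stop_data(paste0("zero exposure effect (Wald ratio undefined) for: ",
                     fmt_ids(dat$rsid[g == 0])))
  }
  list(
    theta = dat$beta_outcome / g,
    # inverse-variance weights of the ratio estimates
    w = g^2 / dat$se_outcome^2
  )
}

#' Per-SNP Wald ratio estimates
#'
#' For each instrument, the causal effect is the outcome association
#' divided by the exposure association; the SE is the first-order delta
#' method `se_outcome / |beta_exposure|`.
#'
#' @param dat Harmonized instrument tibble (see [harmonize()]).
#' @return Tibble with one row per SNP (`rsid`, `method`, `n_snp`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `pval`, `or`, `or_ci_low`, `or_ci_high`).
#' @export
mr_wald_ratio <- function(dat) {
  check_harmonized(dat, 1L, "wald_ratio")
  rs <- ratio_stats(dat)
  b <- rs$theta
  se <- dat$se_outcome / abs(dat$beta_exposure)
  z <- Z95()
  tibble::tibble(
    rsid = dat$rsid, method = "wald", n_snp = 1L,
    beta = b, se = se, ci_low = b - z * se, ci_high = b + z * se,
    pval = 2 * pnorm(-abs(b / se)),
    or = exp(b), or_ci_low = exp(b - z * se), or_ci_high = exp(b + z * se)
  )
}

#' Inverse-variance weighted estimate
#'
#' Combines the per-SNP Wald ratios with inverse-variance weights;
#' equivalently, weighted least-squares regression of the outcome
#' associations on the exposure associations through the origin with
#' weights `1/se_outcome^2`. Under the multiplicative random-effects model
#' (the default) the fixed-effect SE is inflated by
#' `max(1, sqrt(Q/(J - 1)))`, so between-instrument heterogeneity widens
#' the interval but under-dispersion is never rewarded.
#'
#' @param dat Harmonized instrument tibble.
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`. With a single SNP the fixed model is used (and equals the
#'   Wald ratio).
#' @return An `mr_fit` object; `extras` carries `q_stat`, `q_df`,
#'   `q_pval` and the model used.
#' @export
mr_ivw <- function(dat, model = c("random", "fixed")) {
  model <- match.arg(model)
  check_harmonized(dat, 1L, "IVW")
  g <- dat$beta_exposure
  G <- dat$beta_outcome
  if (any(g == 0)) {
    stop_data(paste0("zero exposure effect for: ", fmt_ids(dat$rsid[g == 0])))
  }
  w <- 1 / dat$se_outcome^2
  J <- length(g)
  b <- sum(w * g * G) / sum(w * g^2)
  se_fixed <- sqrt(1 / sum(w * g^2))
  Q <- sum(w * (G - b * g)^2)
  if (J >= 2 && model == "random") {
    se <- se_fixed * max(1, sqrt(Q / (J - 1)))
  } else {
    se <- se_fixed
    if (J < 2) model <- "fixed"
  }
  pval <- 2 * pnorm(-abs(b / se))
  new_mr_fit("ivw", J, b, se, pval, extras = list(
    q_stat = Q, q_df = J - 1L,
    q_pval = if (J >= 2) pchisq(Q, J - 1, lower.tail = FALSE) else NA_real_,
    model = model
  ))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome associations on the exposure
#' associations *with* an intercept, weights `1/se_outcome^2`. The slope
#' estimates the causal effect under the InSIDE assumption; the intercept
#' estimates the average directional pleiotropy. Before fitting, every
#' pair is oriented so the exposure effect is positive (both effects
#' negated where needed), making the fit invariant to arbitrary allele
#' orientation. SEs use multiplicative random-effects scaling with the
#' residual-based Q on `J - 2` degrees of freedom, clipped below at 1;
#' p-values use the t distribution with `J - 2` df.
#'
#' @param dat Harmonized instrument tibble (at least 3 SNPs).
#' @return An `mr_fit` for the slope; `extras` carries `intercept`,
#'   `intercept_se`, `intercept_pval`, `q_stat`, `q_df`, `q_pval`, and a
#'   `collinear` flag when all oriented exposure effects coincide.
#' @export
mr_egger <- function(dat) {
  check_harmonized(dat, 3L, "MR-Egger")
  s <- ifelse(dat$beta_exposure < 0, -1, 1)
  g <- dat$beta_exposure * s
  G <- dat$beta_outcome * s
  w <- 1 / dat$se_outcome^2
  J <- length(g)
  if (sd(g) < .Machine$double.eps^0.5 * max(1, mean(abs(g)))) {
    warn("MR-Egger: oriented exposure effects are (nearly) identical; slope unidentified")
    fit <- new_mr_fit("egger", J, NA_real_, NA_real_, NA_real_,
                      extras = list(collinear = TRUE))
    return(fit)
  }
  m <- lm(G ~ g, weights = w)
  # summary.lm warns on an exact fit; that case is legitimate here
  sm <- suppressWarnings(summary(m))
  sigma <- sm$sigma # sqrt(weighted RSS / (J - 2)) = sqrt(Q_egger / (J - 2))
  scale <- if (sigma > 0) max(1, sigma) / sigma else 1 # exact fit: SEs are 0
  cf <- coef(sm)
  b <- cf["g", "Estimate"]
  se_b <- cf["g", "Std. Error"] * scale
  a <- cf["(Intercept)", "Estimate"]
  se_a <- cf["(Intercept)", "Std. Error"] * scale
  Q <- sigma^2 * (J - 2)
  tp <- function(est, se) {
    if (se > 0) 2 * pt(-abs(est / se), df = J - 2) else as.numeric(est == 0)
  }
  p_b <- tp(b, se_b)
  p_a <- tp(a, se_a)
  new_mr_fit("egger", J, b, se_b, p_b, extras = list(
    intercept = a, intercept_se = se_a, intercept_pval = p_a,
    q_stat = Q, q_df = J - 2L,
    q_pval = pchisq(Q, J - 2, lower.tail = FALSE),
    collinear = FALSE
  ))
}

# weighted median of ratio estimates by cumulative-weight interpolation
weighted_median_point <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  ww <- w[o] / sum(w)
  S <- cumsum(ww)
  p <- S - ww / 2
  if (0.5 <= p[1]) return(th[1])
  n <- length(th)
  if (0.5 >= p[n]) return(th[n])
  approx(p, th, xout = 0.5, ties = "ordered")$y
}

# weighted modal estimate via Gaussian-kernel density of the ratios
weighted_mode_point <- function(theta, w, bandwidth_factor = 1) {
  n <- length(theta)
  s <- 0.9 * min(sd(theta), mad(theta)) * n^(-1 / 5)
  h <- bandwidth_factor * s
  if (!is.finite(h) || h <= 0) return(theta[1]) # all ratios identical
  d <- density(theta, weights = w / sum(w), bw = h, n = 1024)
  d$x[which.max(d$y)]
}

# parametric bootstrap SE shared by the median- and mode-based estimators:
# resample each association from its reported normal sampling distribution
boot_se <- function(dat, point_fun, n_boot, seed) {
  if (missing(seed) || is.null(seed)) {
    stop_config("a `seed` is required for the bootstrap SE")
  }
  if (!is.numeric(n_boot) || n_boot < 2) {
    stop_config("`n_boot` must be at least 2")
  }
  withr::local_seed(as.integer(seed))
  J <- nrow(dat)
  est <- vapply(seq_len(n_boot), function(i) {
    g <- rnorm(J, dat$beta_exposure, dat$se_exposure)
    G <- rnorm(J, dat$beta_outcome, dat$se_outcome)
    g[g == 0] <- .Machine$double.eps
    point_fun(G / g, g^2 / dat$se_outcome^2)
  }, numeric(1))
  sd(est)
}

#' Weighted median estimate
#'
#' The inverse-variance weighted median of the per-SNP Wald ratios:
#' ratios are sorted, weights normalized, and the estimate is the linear
#' interpolation of the ratio at cumulative weight one half (using the
#' cumulative-midpoint convention `S_j - w_j/2`). Consistent when at least
#' half of the total weight comes from valid instruments. The SE is the
#' standard deviation of the estimate over parametric-bootstrap
#' replicates drawing each association from its sampling distribution.
#'
#' @param dat Harmonized instrument tibble (at least 3 SNPs).
#' @param n_boot Bootstrap replicates for the SE (default 1000; must be
#'   at least 2).
#' @param seed Integer seed for the bootstrap (required).
#' @return An `mr_fit`; `extras` carries `n_boot`.
#' @export
mr_weighted_median <- function(dat, n_boot = 1000, seed = NULL) {
  check_harmonized(dat, 3L, "weighted median")
  rs <- ratio_stats(dat)
  b <- weighted_median_point(rs$theta, rs$w)
  se <- boot_se(dat, weighted_median_point, n_boot, seed)
  new_mr_fit("weighted_median", nrow(dat), b, se,
             2 * pnorm(-abs(b / se)),
             extras = list(n_boot = n_boot))
}

#' Weighted mode estimate
#'
#' The mode-based estimate: per-SNP Wald ratios are smoothed with a
#' weighted Gaussian kernel density (bandwidth `phi * 0.9 *
#' min(sd, mad) * J^(-1/5)`, a robust-scale Silverman-type rule) and the
#' estimate is the density's argmax. Consistent when the largest group of
#' instruments sharing the same ratio is valid, even if they carry a
#' minority of the weight. SE by parametric bootstrap, as for the
#' weighted median.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier `phi` on the default bandwidth
#'   (default 1).
#' @return An `mr_fit`; `extras` carries `bandwidth_factor` and `n_boot`.
#' @export
mr_weighted_mode <- function(dat, bandwidth_factor = 1, n_boot = 1000,
                             seed = NULL) {
  check_harmonized(dat, 3L, "weighted mode")
  check_number(bandwidth_factor, "bandwidth_factor", 0, Inf, open_lower = TRUE)
  rs <- ratio_stats(dat)
  b <- weighted_mode_point(rs$theta, rs$w, bandwidth_factor)
  se <- boot_se(dat,
                function(th, w) weighted_mode_point(th, w, bandwidth_factor),
                n_boot, seed)
  new_mr_fit("weighted_mode", nrow(dat), b, se,
             2 * pnorm(-abs(b / se)),
             extras = list(bandwidth_factor = bandwidth_factor,
                           n_boot = n_boot))
}

#' Run all MR estimators on a harmonized set
#'
#' Computes the IVW, MR-Egger, weighted-median and weighted-mode estimates
#' plus the per-SNP Wald ratios. A method whose minimum-SNP precondition is
#' not met is reported as absent (with the reason) rather than failing the
#' run.
#'
#' @param dat Harmonized instrument tibble.
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param seed Integer seed for the bootstraps (required when bootstrap
#'   methods can run).
#' @param ivw_model IVW random-effects flavour, see [mr_ivw()].
#' @param bandwidth_factor Mode bandwidth multiplier, see
#'   [mr_weighted_mode()].
#' @return Tibble of per-method estimates (as [tidy()] rows) with
#'   attributes `fits` (named list of `mr_fit` objects), `singlesnp`
#'   (Wald-ratio tibble) and `absent` (tibble `method`, `reason`).
#' @export
mr_all_methods <- function(dat, n_boot = 1000, seed = NULL,
                           ivw_model = "random", bandwidth_factor = 1) {
  check_harmonized(dat, 1L, "mr_all_methods")
  fits <- list()
  absent <- tibble::tibble(method = character(), reason = character())
  run <- function(method, expr) {
    tryCatch(expr, error = function(e) {
      absent <<- dplyr::bind_rows(absent, tibble::tibble(
        method = method, reason = conditionMessage(e)))
      NULL
    })
  }
  fits$ivw <- run("ivw", mr_ivw(dat, model = ivw_model))
  fits$egger <- run("egger", mr_egger(dat))
  fits$weighted_median <- run(
    "weighted_median", mr_weighted_median(dat, n_boot = n_boot, seed = seed))
  fits$weighted_mode <- run(
    "weighted_mode",
    mr_weighted_mode(dat, bandwidth_factor = bandwidth_factor,
                     n_boot = n_boot, seed = seed))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  est <- dplyr::bind_rows(lapply(fits, tidy))
  singlesnp <- mr_wald_ratio(dat)
  attr(est, "fits") <- fits
  attr(est, "singlesnp") <- singlesnp
  attr(est, "absent") <- absent
  est
}
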