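# MR-PRESSO: residual-sum-and-outlier test for horizontal pleiotropy.
#
# Global test: the observed residual sum of squares around the
# leave-one-out IVW predictions is compared with its parametric-simulation
# distribution under no pleiotropy. Outlier test: each SNP's observed
# squared residual is compared with its own simulated distribution
# (Bonferroni-adjusted). Distortion test: the relative change in the IVW
# estimate after outlier removal is compared with the change produced by
# removing equally many randomly chosen non-outlier SNPs.

# leave-one-out IVW slopes for all j at once (weights 1/se_y^2)
loo_slopes <- function(g, G, w) {
  num <- w * g * G
  den <- w * g^2
  (sum(num) - num) / (sum(den) - den)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' @param dat Harmonized instrument tibble (at least 4 SNPs).
#' @param n_sim Number of parametric simulations for the null
#'   distributions (default 1000).
#' @param significance Level for declaring an outlier on the
#'   Bonferroni-adjusted per-SNP p-value (default 0.05).
#' @param seed Integer seed (required).
#' @return An object of class `mr_presso` with elements `rss_obs`,
#'   `global_pval`, `outliers` (tibble `rsid`, `residual2`, `pval`,
#'   `pval_adj`), `outlier_rsids`, `beta_all`, `beta_no_outliers`,
#'   `distortion_coefficient` (percent), `distortion_pval`,
#'   `distortion_defined`, `n_sim`, `seed`. `glance()` gives a one-row
#'   summary, `tidy()` the per-SNP table.
#' @export
mr_presso <- function(dat, n_sim = 1000, significance = 0.05, seed = NULL) {
  check_harmonized(dat, 4L, "MR-PRESSO")
  check_number(n_sim, "n_sim", 2)
  check_number(significance, "significance", 0, 1, open_lower = TRUE)
  if (is.null(seed)) stop_config("a `seed` is required for MR-PRESSO")
  withr::local_seed(as.integer(seed))

  g <- dat$beta_exposure
  G <- dat$beta_outcome
  sx <- dat$se_exposure
  sy <- dat$se_outcome
  w <- 1 / sy^2
  J <- length(g)

  th_loo <- loo_slopes(g, G, w)
  res_obs2 <- (G - th_loo * g)^2
  rss_obs <- sum(res_obs2)

  # parametric simulations under the no-pleiotropy null
  gs <- matrix(rnorm(J * n_sim, g, sx), nrow = J)
  Gs <- matrix(rnorm(J * n_sim, th_loo * g, sy), nrow = J)
  num <- w * gs * Gs
  den <- w * gs^2
  th_star <- (rep(colSums(num), each = J) - num) /
    (rep(colSums(den), each = J) - den)
  res_star2 <- (Gs - th_star * gs)^2
  rss_star <- colSums(res_star2)

  global_pval <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
  p_snp <- (1 + rowSums(res_star2 >= res_obs2)) / (n_sim + 1)
  p_adj <- pmin(1, p_snp * J)
  out_mask <- p_adj < significance
  outliers <- tibble::tibble(rsid = dat$rsid, residual2 = res_obs2,
                             pval = p_snp, pval_adj = p_adj,
                             outlier = out_mask)

  beta_all <- mr_ivw(dat, model = "random")$b
  n_out <- sum(out_mask)
  beta_no <- NA_real_
  distortion <- NA_real_
  distortion_pval <- NA_real_
  distortion_defined <- FALSE
  if (n_out > 0) {
    remaining <- which(!out_mask)
    if (length(remaining) >= 3 && length(remaining) > 2) {
      beta_no <- mr_ivw(dat[remaining, , drop = FALSE], model = "random")$b
      distortion <- 100 * (beta_no - beta_all) / abs(beta_all)
      distortion_defined <- TRUE
      # null distribution: remove random non-outlier subsets of the same size
      if (length(remaining) > n_out + 2) {
        d_star <- vapply(seq_len(n_sim), function(i) {
          drop <- sample(remaining, n_out)
          b <- mr_ivw(dat[-drop, , drop = FALSE], model = "random")$b
          100 * (b - beta_all) / abs(beta_all)
        }, numeric(1))
        distortion_pval <- (1 + sum(abs(d_star) >= abs(distortion))) /
          (n_sim + 1)
      }
    }
  } else {
    beta_no <- beta_all
    distortion <- 0
  }

  structure(list(
    rss_obs = rss_obs, global_pval = global_pval,
    outliers = outliers, outlier_rsids = dat$rsid[out_mask],
    beta_all = beta_all, beta_no_outliers = beta_no,
    distortion_coefficient = distortion, distortion_pval = distortion_pval,
    distortion_defined = distortion_defined,
    n_sim = n_sim, significance = significance, seed = seed, n_snp = J
  ), class = "mr_presso")
}

#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) x$outliers

#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(
    rss_obs = x$rss_obs, global_pval = x$global_pval,
    n_outliers = length(x$outlier_rsids),
    beta_all = x$beta_all, beta_no_outliers = x$beta_no_outliers,
    distortion_coefficient = x$distortion_coefficient,
    distortion_pval = x$distortion_pval,
    n_sim = x$n_sim, n_snp = x$n_snp
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO (%d SNPs, %d simulations)\n", x$n_snp, x$n_sim))
  cat(sprintf("  global test: RSS = %.4g, p = %.4g\n", x$rss_obs,
              x$global_pval))
  cat(sprintf("  outliers: %d%s\n", length(x$outlier_rsids),
              if (length(x$outlier_rsids) > 0) {
                paste0(" (", fmt_ids(x$outlier_rsids), ")")
              } else ""))
  if (x$distortion_defined) {
    cat(sprintf("  distortion: %.2f%% (p = %.4g)\n",
                x$distortion_coefficient, x$distortion_pval))
  }
  invisible(x)
}

#' Full sensitivity report for a harmonized instrument set
#'
#' Bundles Cochran's Q, the Egger-intercept test, MR-PRESSO and the
#' leave-one-out analysis.
#'
#' @param dat Harmonized instrument tibble.
#' @param n_sim MR-PRESSO simulation count.
#' @param significance MR-PRESSO outlier significance level.
#' @param seed Integer seed for MR-PRESSO.
#' @return Named list (`q`, `pleiotropy`, `presso`, `loo`); components
#'   whose SNP-count preconditions fail are `NULL`.
#' @export
mr_sensitivity <- function(dat, n_sim = 1000, significance = 0.05,
                           seed = NULL) {
  list(
    q = if (nrow(dat) >= 2) mr_cochran_q(dat) else NULL,
    pleiotropy = if (nrow(dat) >= 3) mr_pleiotropy_test(dat) else NULL,
    presso = if (nrow(dat) >= 4) {
      mr_presso(dat, n_sim = n_sim, significance = significance, seed = seed)
    } else NULL,
    loo = if (nrow(dat) >= 3) mr_leave_one_out(dat) else NULL
  )
}
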