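# Asymptotic power for two-sample MR with a binary outcome.
#
# The IVW estimator's sampling variance is approximately
#   1 / (n * R2 * cf * (1 - cf))
# where n is the outcome sample size, cf the case fraction and R2 the
# variance in the (SD-scaled) exposure explained by the instruments, so
# the two-sided test of a true causal log-odds b per SD has non-centrality
#   ncp = |b| * sqrt(n * R2 * cf * (1 - cf)).

#' Power of a two-sample MR analysis with a binary outcome
#'
#' Asymptotic power of the two-sided IVW test at level `alpha`:
#' `power = Phi(ncp - z) + Phi(-ncp - z)` with `z = qnorm(1 - alpha/2)`
#' and the non-centrality above. At `detectable_or = 1` the power equals
#' `alpha`; power is strictly increasing in `|log(detectable_or)|`, `n`
#' and `r2_instruments`.
#'
#' @param n_outcome Outcome study sample size (cases + controls).
#' @param case_fraction Proportion of cases in the outcome study.
#' @param r2_instruments Variance in the exposure explained by the
#'   instruments.
#' @param detectable_or Hypothesized true odds ratio(s) per 1 SD of
#'   exposure; vectorized.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Tibble (`or`, `ncp`, `power`).
#' @export
mr_power_binary <- function(n_outcome, case_fraction, r2_instruments,
                            detectable_or, alpha = 0.05) {
  check_number(n_outcome, "n_outcome", 1)
  check_number(case_fraction, "case_fraction", 0, 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(r2_instruments, "r2_instruments", 0, 1, open_lower = TRUE,
               open_upper = TRUE)
  check_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(detectable_or, "detectable_or", 0, Inf, open_lower = TRUE)
  b <- log(detectable_or)
  ncp <- abs(b) * sqrt(n_outcome * r2_instruments *
                         case_fraction * (1 - case_fraction))
  z <- qnorm(1 - alpha / 2)
  tibble::tibble(
    or = detectable_or,
    ncp = ncp,
    power = pnorm(ncp - z) + pnorm(-ncp - z)
  )
}

#' Smallest odds ratio detectable at a given power
#'
#' Inverse of [mr_power_binary()] in `detectable_or`: the odds ratios
#' (one protective, one risk-increasing) at which the analysis reaches
#' `power`.
#'
#' @inheritParams mr_power_binary
#' @param power Target power in (alpha, 1) (default 0.8).
#' @return One-row tibble (`or_protective`, `or_risk`, `power`).
#' @export
mr_detectable_or <- function(n_outcome, case_fraction, r2_instruments,
                             alpha = 0.05, power = 0.8) {
  check_number(power, "power", alpha, 1, open_lower = TRUE, open_upper = TRUE)
  f <- function(b) {
    mr_power_binary(n_outcome, case_fraction, r2_instruments,
                    exp(b), alpha = alpha)$power - power
  }
  b <- uniroot(f, lower = 1e-10, upper = 10, tol = 1e-10)$root
  tibble::tibble(or_protective = exp(-b), or_risk = exp(b), power = power)
}
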