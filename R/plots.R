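# ggplot2 visualizations: single-SNP forest, method scatter, and the
# multi-analysis odds-ratio forest.

#' Forest plot of single-SNP Wald ratios with the pooled IVW estimate
#'
#' @param singlesnp Tibble from [mr_wald_ratio()].
#' @param ivw_fit Optional `mr_fit` from [mr_ivw()] plotted as the summary
#'   row.
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(singlesnp, ivw_fit = NULL) {
  d <- dplyr::arrange(tibble::as_tibble(singlesnp), .data$beta)
  d$label <- d$rsid
  d$pooled <- FALSE
  if (!is.null(ivw_fit)) {
    d <- dplyr::bind_rows(d, tibble::tibble(
      label = "All (IVW)", beta = ivw_fit$b, ci_low = ivw_fit$ci_low,
      ci_high = ivw_fit$ci_high, pooled = TRUE))
  }
  d$label <- factor(d$label, levels = d$label)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$label,
                                  colour = .data$pooled)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "MR effect size (log odds per SD exposure)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of outcome vs exposure associations with method fits
#'
#' Each point is one instrument (error bars are +/- 1 SE on both axes);
#' each line is one estimator's fitted relationship. Points are oriented
#' so the exposure association is positive, matching the Egger
#' orientation convention.
#'
#' @param dat Harmonized instrument tibble.
#' @param estimates Tibble from [mr_all_methods()].
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(dat, estimates) {
  s <- ifelse(dat$beta_exposure < 0, -1, 1)
  d <- tibble::tibble(
    g = dat$beta_exposure * s, G = dat$beta_outcome * s,
    se_g = dat$se_exposure, se_G = dat$se_outcome
  )
  fits <- attr(estimates, "fits") %||% list()
  lines <- purrr::map_dfr(fits, function(f) {
    if (is.na(f$b)) return(NULL)
    tibble::tibble(method = f$method, slope = f$b,
                   intercept = f$extras$intercept %||% 0)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$g, y = .data$G)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$G - .data$se_G,
                                        ymax = .data$G + .data$se_G),
                           colour = "grey70", width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$g - .data$se_g,
                                         xmax = .data$g + .data$se_g),
                            colour = "grey70", height = 0) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method)) +
    ggplot2::labs(x = "SNP effect on exposure (SD)",
                  y = "SNP effect on outcome (log odds)",
                  colour = "MR method") +
    ggplot2::theme_minimal()
}

#' Forest plot of odds ratios across main and sensitivity analyses
#'
#' @param cmp Tibble from [mr_comparison_table()].
#' @return A ggplot object.
#' @export
plot_mr_comparison_forest <- function(cmp) {
  d <- tibble::as_tibble(cmp)
  d$analysis <- factor(d$analysis, levels = rev(unique(d$analysis)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$analysis,
                                  colour = .data$method)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$or_ci_low, xmax = .data$or_ci_high),
      height = 0.25, position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "OR per 1 SD increase in exposure", y = NULL,
                  colour = "MR method") +
    ggplot2::theme_minimal()
}

#' @method autoplot mr_report
#' @export
autoplot.mr_report <- function(object,
                               type = c("scatter", "forest", "comparison"),
                               ...) {
  type <- match.arg(type)
  switch(type,
    scatter = plot_mr_scatter(object$instruments, object$estimates),
    forest = plot_mr_forest(object$singlesnp,
                            attr(object$estimates, "fits")$ivw),
    comparison = plot_mr_comparison_forest(mr_comparison_table(object))
  )
}
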