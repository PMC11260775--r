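# Orchestration of the full analysis: select -> clump -> proxy ->
# harmonize -> estimate -> sensitivity -> power, with a written report
# bundle.

#' Build a pipeline run configuration
#'
#' Collects every threshold, estimator setting and path used by
#' [run_mr_pipeline()], with the conventional defaults: genome-wide
#' selection at `p < 5e-8`, clumping at r^2 0.001 within +/- 10,000 kb,
#' proxies at r^2 >= 0.8, palindromic inference below MAF 0.3.
#'
#' @param exposure,outcome Summary-statistics tibbles or paths to TSVs.
#' @param panel An [ld_panel()], or `NULL` to skip clumping/proxy search.
#' @param annotations Annotation tibble/path, or `NULL` to skip category
#'   analyses.
#' @param output_dir Directory for the report bundle, or `NULL` to skip
#'   writing.
#' @param p_select,clump_r2,clump_window_kb,proxy_min_r2,palindromic_maf
#'   Selection/harmonization thresholds.
#' @param ivw_model,n_boot,bandwidth_factor Estimator settings.
#' @param presso_n_sim,presso_significance MR-PRESSO settings.
#' @param categories Trait categories for exclusion runs (default: the
#'   five analysis categories).
#' @param keep_only_categories Categories additionally analysed keep-only.
#' @param exclusion_labels Named labels for the comparison forest plot.
#' @param n_exposure Exposure GWAS sample size for instrument strength
#'   (defaults to the exposure table's `n_total` attribute).
#' @param n_case,n_control Outcome case/control counts; required for the
#'   power curve (skipped when absent).
#' @param power_or_grid Odds-ratio grid for the power curve.
#' @param alpha Significance level for the power curve.
#' @param seed Integer seed covering every stochastic component.
#' @param write_plots Also render the three figures as PDFs.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(exposure, outcome, panel = NULL, annotations = NULL,
                      output_dir = NULL,
                      p_select = 5e-8, clump_r2 = 0.001,
                      clump_window_kb = 10000, proxy_min_r2 = 0.8,
                      palindromic_maf = 0.3,
                      ivw_model = "random", n_boot = 1000,
                      bandwidth_factor = 1,
                      presso_n_sim = 1000, presso_significance = 0.05,
                      categories = setdiff(mr_trait_categories(), "other"),
                      keep_only_categories = c("blood", "inflammation"),
                      exclusion_labels = c(
                        proxy = "AXP", blood = "AXB",
                        body_composition = "AXBC", inflammation = "AXI",
                        lipid = "AXL", type_2_diabetes = "AXT2D"),
                      n_exposure = NULL, n_case = NULL, n_control = NULL,
                      power_or_grid = c(0.8, 0.9, 1.1, 1.2, 1.5),
                      alpha = 0.05,
                      seed = NULL,
                      write_plots = TRUE) {
  check_number(p_select, "p_select", 0, 1, open_lower = TRUE)
  check_number(clump_r2, "clump_r2", 0, 1)
  check_number(proxy_min_r2, "proxy_min_r2", 0, 1)
  check_number(palindromic_maf, "palindromic_maf", 0, 0.5)
  check_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (is.null(seed)) stop_config("a `seed` is required")
  structure(list(
    exposure = exposure, outcome = outcome, panel = panel,
    annotations = annotations, output_dir = output_dir,
    p_select = p_select, clump_r2 = clump_r2,
    clump_window_kb = clump_window_kb, proxy_min_r2 = proxy_min_r2,
    palindromic_maf = palindromic_maf,
    ivw_model = ivw_model, n_boot = n_boot,
    bandwidth_factor = bandwidth_factor,
    presso_n_sim = presso_n_sim,
    presso_significance = presso_significance,
    categories = categories,
    keep_only_categories = keep_only_categories,
    exclusion_labels = exclusion_labels,
    n_exposure = n_exposure, n_case = n_case, n_control = n_control,
    power_or_grid = power_or_grid, alpha = alpha,
    seed = as.integer(seed), write_plots = isTRUE(write_plots)
  ), class = "mr_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirroring the arguments of [mr_config()]; `exposure`,
#' `outcome`, `annotations` are file paths, the panel is given as
#' `panel_genotypes` + `panel_info` paths.
#'
#' @param path YAML file.
#' @param ... Overrides passed on to [mr_config()].
#' @return A list of class `mr_config`.
#' @export
read_mr_config <- function(path, ...) {
  if (!file.exists(path)) stop_config(paste0("file not found: ", path))
  y <- yaml::read_yaml(path)
  panel <- NULL
  if (!is.null(y$panel_genotypes)) {
    panel <- read_ld_panel(y$panel_genotypes, y$panel_info)
    y$panel_genotypes <- NULL
    y$panel_info <- NULL
  }
  y$panel <- panel
  y <- modifyList(y, list(...))
  do.call(mr_config, y)
}

load_table <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full two-sample MR pipeline
#'
#' Executes instrument selection, LD clumping, proxy substitution,
#' harmonization, the four-estimator analysis, the sensitivity battery
#' (Cochran's Q, Egger intercept, MR-PRESSO, leave-one-out, proxy and
#' trait-category exclusion, keep-only runs), instrument strength and the
#' power curve, in that order. When `output_dir` is set, writes TSVs of
#' every result table, the harmonization audit, a JSON summary, a log of
#' every configuration value used, and (optionally) the three figures
#' with their underlying plot-data tables.
#'
#' @param config An [mr_config()].
#' @return A list of class `mr_report` with elements `instruments`,
#'   `estimates`, `singlesnp`, `strength`, `sensitivity`, `exclusions`,
#'   `keep_only`, `power`, `audit`, `proxy_log`, `clump_log`, `config`.
#' @export
run_mr_pipeline <- function(config) {
  stopifnot(inherits(config, "mr_config"))
  cfg <- config
  exposure <- load_table(cfg$exposure, read_summary_stats)
  outcome <- load_table(cfg$outcome, read_summary_stats)
  annotations <- if (!is.null(cfg$annotations)) {
    load_table(cfg$annotations, read_annotations)
  }

  # 1. selection + clumping
  clump_log <- NULL
  if (!is.null(cfg$panel)) {
    exposure <- ld_clump(exposure, cfg$panel, p_threshold = cfg$p_select,
                         r2_threshold = cfg$clump_r2,
                         window_kb = cfg$clump_window_kb)
    clump_log <- attr(exposure, "clump_log")
  } else {
    exposure <- exposure[exposure$pval < cfg$p_select, , drop = FALSE]
  }
  if (nrow(exposure) == 0) stop_data("selection stage: no instruments pass")

  # 2. proxy substitution
  proxy_log <- NULL
  if (!is.null(cfg$panel)) {
    outcome <- substitute_proxies(exposure, outcome, cfg$panel,
                                  min_r2 = cfg$proxy_min_r2)
    proxy_log <- attr(outcome, "proxy_log")
  }

  # 3. harmonization
  dat <- harmonize(exposure, outcome, maf_threshold = cfg$palindromic_maf)
  audit <- harmonization_audit(dat)
  if (nrow(dat) == 0) stop_data("harmonization stage: no instruments left")

  # 4. instrument strength
  n_exp <- cfg$n_exposure %||% attr(exposure, "n_total")
  strength <- if (!is.null(n_exp)) {
    instrument_strength(dat, n = n_exp)
  }

  # 5. estimators
  estimates <- mr_all_methods(dat, n_boot = cfg$n_boot, seed = cfg$seed,
                              ivw_model = cfg$ivw_model,
                              bandwidth_factor = cfg$bandwidth_factor)
  singlesnp <- attr(estimates, "singlesnp")

  # 6. sensitivity battery
  sens <- mr_sensitivity(dat, n_sim = cfg$presso_n_sim,
                         significance = cfg$presso_significance,
                         seed = cfg$seed)
  exclusions <- NULL
  keep_only <- NULL
  if (!is.null(annotations) && length(cfg$categories) > 0 && nrow(dat) > 0) {
    exclusions <- mr_category_exclusion(
      dat, annotations, categories = cfg$categories, mode = "exclude",
      n_boot = cfg$n_boot, seed = cfg$seed, ivw_model = cfg$ivw_model,
      bandwidth_factor = cfg$bandwidth_factor)
    if (length(cfg$keep_only_categories) > 0) {
      keep_only <- mr_category_exclusion(
        dat, annotations, categories = cfg$keep_only_categories,
        mode = "keep_only", n_boot = cfg$n_boot, seed = cfg$seed,
        ivw_model = cfg$ivw_model,
        bandwidth_factor = cfg$bandwidth_factor)
    }
  }
  proxy_excl <- NULL
  if (any(dat$is_proxy)) {
    sub <- dat[!dat$is_proxy, , drop = FALSE]
    if (nrow(sub) > 0) {
      proxy_excl <- mr_all_methods(sub, n_boot = cfg$n_boot, seed = cfg$seed,
                                   ivw_model = cfg$ivw_model,
                                   bandwidth_factor = cfg$bandwidth_factor)
    }
  }

  # 7. power
  power <- NULL
  if (!is.null(cfg$n_case) && !is.null(cfg$n_control) &&
      !is.null(strength)) {
    n_out <- cfg$n_case + cfg$n_control
    cf <- cfg$n_case / n_out
    power <- list(
      curve = mr_power_binary(n_out, cf, strength$r2_total,
                              cfg$power_or_grid, alpha = cfg$alpha),
      detectable = mr_detectable_or(n_out, cf, strength$r2_total,
                                    alpha = cfg$alpha, power = 0.8)
    )
  }

  report <- structure(list(
    instruments = dat, estimates = estimates, singlesnp = singlesnp,
    strength = strength, sensitivity = sens,
    exclusions = exclusions, keep_only = keep_only,
    proxy_exclusion = proxy_excl,
    power = power, audit = audit, proxy_log = proxy_log,
    clump_log = clump_log, config = cfg
  ), class = "mr_report")

  if (!is.null(cfg$output_dir)) write_mr_report(report, cfg$output_dir)
  report
}

#' Comparison table across the main and exclusion analyses
#'
#' One row per analysis/method with odds ratios, in the layout of a
#' multi-analysis forest plot. Analyses are labelled with the configured
#' codes (main analysis = `"Main"`, proxy exclusion = `"AXP"`, category
#' exclusions per `exclusion_labels`).
#'
#' @param report An `mr_report`.
#' @return Tibble (`analysis`, `method`, `n_snp`, `or`, `or_ci_low`,
#'   `or_ci_high`, `pval`).
#' @export
mr_comparison_table <- function(report) {
  labels <- report$config$exclusion_labels
  pick <- c("method", "n_snp", "or", "or_ci_low", "or_ci_high", "pval")
  out <- list(dplyr::mutate(report$estimates[pick], analysis = "Main",
                            .before = 1))
  if (!is.null(report$proxy_exclusion)) {
    out <- c(out, list(dplyr::mutate(
      report$proxy_exclusion[pick],
      analysis = unname(labels["proxy"] %||% "AXP"), .before = 1)))
  }
  if (!is.null(report$exclusions)) {
    ex <- report$exclusions[!is.na(report$exclusions$method), , drop = FALSE]
    lab <- unname(labels[ex$category])
    lab[is.na(lab)] <- paste0("AX:", ex$category[is.na(lab)])
    out <- c(out, list(dplyr::mutate(ex[pick], analysis = lab, .before = 1)))
  }
  dplyr::bind_rows(out)
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Two-sample MR report\n")
  cat(sprintf("  instruments: %d (of %d exposure signals)\n",
              nrow(x$instruments), nrow(x$audit)))
  if (!is.null(x$strength)) {
    cat(sprintf("  instrument strength: R2 = %.3f, F = %.1f\n",
                x$strength$r2_total, x$strength$f_statistic))
  }
  print(x$estimates[c("method", "n_snp", "or", "or_ci_low", "or_ci_high",
                      "pval")])
  invisible(x)
}

write_mr_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) {
    if (!is.null(x) && is.data.frame(x)) {
      readr::write_tsv(x, file.path(dir, name), progress = FALSE)
    }
  }
  w(report$estimates, "mr_estimates.tsv")
  w(report$singlesnp, "mr_singlesnp.tsv")
  w(report$audit, "harmonization_audit.tsv")
  w(report$proxy_log, "proxy_log.tsv")
  w(report$clump_log, "clump_log.tsv")
  sens <- report$sensitivity
  if (!is.null(sens$q)) w(sens$q, "heterogeneity.tsv")
  if (!is.null(sens$pleiotropy)) w(sens$pleiotropy, "egger_intercept.tsv")
  if (!is.null(sens$presso)) {
    w(glance(sens$presso), "presso_summary.tsv")
    w(tidy(sens$presso), "presso_per_snp.tsv")
  }
  if (!is.null(sens$loo)) w(sens$loo, "leave_one_out.tsv")
  w(report$exclusions, "category_exclusions.tsv")
  w(report$keep_only, "category_keep_only.tsv")
  if (!is.null(report$power)) {
    w(report$power$curve, "power_curve.tsv")
    w(report$power$detectable, "power_detectable_or.tsv")
  }
  cmp <- mr_comparison_table(report)
  w(cmp, "comparison_forest_data.tsv")
  if (!is.null(report$strength)) {
    w(glance(report$strength), "instrument_strength.tsv")
    w(tidy(report$strength), "instrument_strength_per_snp.tsv")
  }

  # structured machine-readable summary
  cfg <- report$config
  cfg_log <- cfg[setdiff(names(cfg), c("exposure", "outcome", "panel",
                                       "annotations"))]
  summary <- list(
    config = cfg_log,
    n_instruments = nrow(report$instruments),
    estimates = report$estimates,
    heterogeneity = sens$q,
    egger_intercept = sens$pleiotropy,
    presso = if (!is.null(sens$presso)) glance(sens$presso),
    strength = if (!is.null(report$strength)) glance(report$strength)
  )
  jsonlite::write_json(summary, file.path(dir, "mr_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  yaml::write_yaml(cfg_log, file.path(dir, "run_config.yaml"))

  if (isTRUE(cfg$write_plots)) {
    save_plot <- function(p, name, width = 7, height = 6) {
      grDevices::pdf(file.path(dir, name), width = width, height = height)
      print(p)
      grDevices::dev.off()
    }
    fits <- attr(report$estimates, "fits")
    save_plot(plot_mr_forest(report$singlesnp, fits$ivw),
              "forest_singlesnp.pdf", height = max(4, nrow(report$singlesnp) * 0.18))
    save_plot(plot_mr_scatter(report$instruments, report$estimates),
              "scatter_methods.pdf")
    save_plot(plot_mr_comparison_forest(cmp), "forest_analyses.pdf")
    w(report$singlesnp, "forest_singlesnp_data.tsv")
    w(report$instruments[c("rsid", "beta_exposure", "se_exposure",
                           "beta_outcome", "se_outcome")],
      "scatter_methods_data.tsv")
  }
  invisible(dir)
}
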