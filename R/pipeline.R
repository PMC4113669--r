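#' Run the full root-vigor classification pipeline
#'
#' One-command orchestration of the analysis flow: load -> QC -> impute ->
#' GRM + summary -> full-data threshold fit (heritability, LRT) -> repeated
#' cross-validation (plus an optional fixed-heritability sweep) -> single-SNP
#' scan + LD summaries. Every stage's output is written under `out_dir`, and a
#' machine-readable `run_summary.json` plus a human-readable `run_log.txt`
#' (seeds, stage results, QC removals, convergence flags) conclude the run.
#' Any stage failure aborts with the stage name; outputs of completed stages
#' are kept.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{genotypes, markers, samples}{input TSV paths (table dialect), or
#'       alternatively `panel` = a [genotype_panel()] object}
#'     \item{max_snp_missing, min_maf}{QC thresholds (defaults 0.15, 0.025)}
#'     \item{k, repeats, seed}{CV settings (defaults 5, 100, 1)}
#'     \item{fixed_h2}{optional numeric vector of heritabilities for the
#'       sensitivity sweep}
#'     \item{impute_k, impute_min_r2}{imputer settings (defaults 5, 0.1)}
#'     \item{out_dir}{output directory}
#'   }
#' @return object of class `run_report`: per-stage summaries and output paths
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  log_lines <- c(sprintf("vigorclass pipeline run, seed %d", seed),
                 sprintf("package version %s",
                         as.character(utils::packageVersion("vigorclass"))))
  report <- list(seed = seed)
  logf <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, file.path(out_dir, "run_log.txt"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # load
  panel <- stage("load", {
    if (!is.null(config$panel)) {
      stopifnot(inherits(config$panel, "genotype_panel"))
      config$panel
    } else {
      load_genotypes(config$genotypes, format = config$format %||% "table",
                     map_path = config$markers, sample_path = config$samples)
    }
  })
  logf("loaded panel: %d samples x %d markers", nrow(panel$genotypes),
       ncol(panel$genotypes))

  # qc
  qc <- stage("qc", qc_filter(panel,
                              max_snp_missing = config$max_snp_missing %||% 0.15,
                              min_maf = config$min_maf %||% 0.025))
  panel <- qc$panel
  report$qc <- qc$report
  logf("QC: removed %d samples, %d markers; %d missing cells of %d (%.2f%%)",
       nrow(qc$report$removed_samples), nrow(qc$report$removed_markers),
       qc$report$n_missing, qc$report$n_cells, qc$report$missing_pct)
  utils::write.table(qc$report$removed_markers,
                     file.path(out_dir, "qc_removed_markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(qc$report$removed_samples,
                     file.path(out_dir, "qc_removed_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # imputation
  panel <- stage("impute", impute_missing(panel,
                                          k = config$impute_k %||% 5L,
                                          min_r2 = config$impute_min_r2 %||% 0.1))
  n_imp <- nrow(attr(panel, "imputed_cells"))
  logf("imputation: filled %d cells", n_imp)
  write_panel(panel, file.path(out_dir, "imputed_panel"))

  # GRM
  grm <- stage("grm", compute_grm(panel, missing_policy = "require_complete"))
  gsum <- grm_summary(grm, panel$samples)
  report$grm_summary <- gsum
  logf("GRM: mean off-diagonal %.3f (SD %.3f)", gsum$mean_offdiag, gsum$sd_offdiag)
  write_grm(grm, file.path(out_dir, "grm.tsv"))

  # full-data fit + LRT
  fit <- stage("fit", fit_threshold_model(panel$samples$vigor_class, grm))
  lrt <- likelihood_ratio_test(fit)
  report$fit <- list(mu = fit$mu, sigma_a2 = fit$sigma_a2, h2 = fit$h2,
                     h2_se = fit$h2_se, converged = fit$converged,
                     lrt_statistic = lrt$statistic, lrt_p = lrt$p_value)
  logf("fit: sigma_a2 %.4f h2 %.3f (SE %.3f), LRT stat %.2f p %.3g, converged %s",
       fit$sigma_a2, fit$h2, fit$h2_se, lrt$statistic, lrt$p_value, fit$converged)
  write_fit_summary(fit, file.path(out_dir, "fit_summary.tsv"))

  # cross-validation
  cv <- stage("cv", run_repeated_cv(panel, grm,
                                    k = config$k %||% 5L,
                                    repeats = config$repeats %||% 100L,
                                    rng_seed = stage_seed(seed, 2L)))
  report$cv <- list(cv_error = cv$cv_error, pooled_error = cv$pooled_error,
                    n_misclassified = cv$n_misclassified,
                    n_test_total = cv$n_test_total, n_skipped = cv$n_skipped)
  logf("CV: error %.6f (%d/%d misclassified, %d replicates skipped)",
       cv$cv_error, cv$n_misclassified, cv$n_test_total, cv$n_skipped)
  write_cv_result(cv, file.path(out_dir, "cv"))
  utils::write.table(per_line_error_summary(cv),
                     file.path(out_dir, "cv", "cv_per_line.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # fixed-heritability sensitivity sweep
  if (!is.null(config$fixed_h2)) {
    sweep_res <- lapply(config$fixed_h2, function(h2) {
      cvh <- stage(paste0("cv_fixed_h2_", h2),
                   run_repeated_cv(panel, grm,
                                   k = config$k %||% 5L,
                                   repeats = config$repeats %||% 100L,
                                   mode = "fixed_h2", h2_fixed = h2,
                                   rng_seed = stage_seed(seed, 3L)))
      logf("CV at fixed h2 %.3f: error %.6f", h2, cvh$cv_error)
      list(h2 = h2, cv_error = cvh$cv_error,
           median_error = stats::median(cvh$replicate_errors))
    })
    report$fixed_h2_sweep <- sweep_res
    utils::write.table(
      data.frame(h2 = vapply(sweep_res, `[[`, numeric(1), "h2"),
                 cv_error = vapply(sweep_res, `[[`, numeric(1), "cv_error"),
                 median_error = vapply(sweep_res, `[[`, numeric(1), "median_error")),
      file.path(out_dir, "cv_fixed_h2_sweep.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # association scan + LD
  scan <- stage("gwas", single_snp_scan(panel))
  utils::write.table(scan, file.path(out_dir, "snp_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ld <- stage("ld", ld_matrix(panel))
  lds <- ld_summaries(ld, large_effect_ids = top_effect_markers(scan))
  report$ld <- lds
  logf("LD: total mean r2 %.3f, within-scaffold %.3f, large-effect %.3f",
       lds$mean_total, lds$mean_within_scaffold, lds$mean_large_effect)

  # run summary
  summary_out <- list(
    seed = seed,
    qc = list(n_samples = qc$report$n_samples, n_markers = qc$report$n_markers,
              n_missing = qc$report$n_missing, n_cells = qc$report$n_cells,
              missing_pct = qc$report$missing_pct),
    grm = list(mean_offdiag = gsum$mean_offdiag, sd_offdiag = gsum$sd_offdiag),
    fit = report$fit,
    cv = report$cv,
    ld = lds
  )
  jsonlite::write_json(summary_out, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run (seed", x$seed, ")\n")
  cat(sprintf("  QC: %d samples x %d markers\n", x$qc$n_samples, x$qc$n_markers))
  cat(sprintf("  h2 = %.3f (SE %.3f), LRT p = %.3g\n",
              x$fit$h2, x$fit$h2_se, x$fit$lrt_p))
  cat(sprintf("  CV error = %.6f (%d/%d)\n", x$cv$cv_error,
              x$cv$n_misclassified, x$cv$n_test_total))
  invisible(x)
}
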