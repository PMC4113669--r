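#' Random k-fold partition
#'
#' Splits `1:n` into k disjoint random subsets whose sizes differ by at most
#' one, deterministic under the seed.
#'
#' @param n number of observations
#' @param k number of folds (2 <= k <= n)
#' @param rng_seed integer seed
#' @return list of k integer index vectors partitioning `1:n`
#' @export
make_folds <- function(n, k, rng_seed) {
  if (k > n) stop("k (", k, ") cannot exceed n (", n, ")")
  if (k < 2L) stop("k must be at least 2")
  perm <- with_seed(rng_seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(perm, rep(seq_len(k), times = sizes))
}

#' Test-set classification error rate
#'
#' \eqn{ER(n) = \frac{1}{n}\sum_i I(y_i \neq \hat y_i)}: the fraction of test
#' observations whose predicted class differs from the observed one.
#'
#' @param true observed 0/1 classes
#' @param predicted predicted 0/1 classes, same length
#' @return error rate in [0, 1]
#' @export
test_error_rate <- function(true, predicted) {
  if (length(true) == 0L) stop("empty test set")
  if (length(true) != length(predicted)) stop("length mismatch")
  mean(true != predicted)
}

#' Repeated k-fold cross-validation of the threshold classifier
#'
#' For each repeat the samples are randomly split into k folds; in turn each
#' fold's phenotypes are set to missing, the threshold model is refitted on
#' the remaining folds (re-estimating \eqn{\sigma_a^2} unless a fixed
#' heritability is imposed or `reestimate = FALSE`), and the held-out samples
#' are classified. The GRM is computed once on all samples and reused across
#' folds: relationships are phenotype-free, so no information leaks from test
#' to training. Each fold contributes one test error rate ER; the CV error is
#' their plain average over all k x repeats replicates. Folds whose training
#' portion contains a single class are skipped with a warning and counted.
#'
#' @param panel a [genotype_panel()] with all samples phenotyped
#' @param grm a [compute_grm()] result aligned with the panel (computed from
#'   the panel if NULL)
#' @param k folds per repeat (default 5)
#' @param repeats number of random re-partitions (default 100)
#' @param mode,h2_fixed passed to [fit_threshold_model()]
#' @param rng_seed integer seed driving all partitions
#' @param reestimate refit \eqn{\sigma_a^2} in every training fold (default
#'   TRUE; ignored in fixed-h2 mode). `FALSE` freezes it at the full-data
#'   estimate for speed.
#' @param stratify stratify folds by class (default FALSE: plain random split)
#' @return object of class `cv_result`: `replicate_errors` (one ER per fold x
#'   repeat), `cv_error` (their mean), `pooled_error`
#'   (misclassified/total), `n_test_total`, `n_misclassified`,
#'   `misclassified_ledger` (replicate, sample_id, line_id, true, predicted),
#'   `line_test_counts`, `n_skipped`, `seed`
#' @export
run_repeated_cv <- function(panel, grm = NULL, k = 5L, repeats = 100L,
                            mode = c("estimate", "fixed_h2"), h2_fixed = NULL,
                            rng_seed = 1L, reestimate = TRUE, stratify = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  mode <- match.arg(mode)
  y <- panel$samples$vigor_class
  if (anyNA(y)) stop("all samples must be phenotyped for cross-validation")
  n <- length(y)
  if (is.null(grm)) grm <- compute_grm(panel)
  if (!identical(as.character(grm$sample_ids), as.character(panel$samples$sample_id))) {
    stop("GRM is not aligned with the panel")
  }
  decomp <- grm_decomp(grm)

  sigma2_frozen <- NULL
  if (mode == "estimate" && !reestimate) {
    full <- fit_threshold_model(y, decomp, mode = "estimate", se_h2 = FALSE)
    sigma2_frozen <- heritability(full$sigma_a2)
  }

  errors <- numeric(0)
  ledger <- list()
  line_counts <- stats::setNames(rep(0L, length(unique(panel$samples$line_id))),
                                 unique(panel$samples$line_id))
  n_test_total <- 0L
  n_skipped <- 0L
  replicate_id <- 0L

  for (r in seq_len(repeats)) {
    folds <- if (stratify) {
      make_stratified_folds(y, k, stage_seed(rng_seed, r))
    } else {
      make_folds(n, k, stage_seed(rng_seed, r))
    }
    for (f in seq_along(folds)) {
      replicate_id <- replicate_id + 1L
      test_idx <- folds[[f]]
      y_train <- y
      y_train[test_idx] <- NA_integer_
      if (length(unique(y_train[!is.na(y_train)])) < 2L) {
        warning("replicate ", replicate_id, ": training fold has a single class; skipped")
        n_skipped <- n_skipped + 1L
        next
      }
      fit <- if (mode == "fixed_h2") {
        fit_threshold_model(y_train, decomp, mode = "fixed_h2", h2_fixed = h2_fixed)
      } else if (!is.null(sigma2_frozen)) {
        fit_threshold_model(y_train, decomp, mode = "fixed_h2", h2_fixed = sigma2_frozen)
      } else {
        fit_threshold_model(y_train, decomp, mode = "estimate", se_h2 = FALSE)
      }
      ids <- panel$samples$sample_id[test_idx]
      pred <- classify(fit, ids)$predicted_class
      errors <- c(errors, test_error_rate(y[test_idx], pred))
      n_test_total <- n_test_total + length(test_idx)
      tl <- table(panel$samples$line_id[test_idx])
      line_counts[names(tl)] <- line_counts[names(tl)] + as.integer(tl)
      wrong <- which(pred != y[test_idx])
      if (length(wrong)) {
        ledger[[length(ledger) + 1L]] <- data.frame(
          replicate = replicate_id,
          sample_id = ids[wrong],
          line_id = panel$samples$line_id[test_idx][wrong],
          true = y[test_idx][wrong],
          predicted = pred[wrong],
          stringsAsFactors = FALSE
        )
      }
    }
  }

  ledger <- if (length(ledger)) do.call(rbind, ledger) else {
    data.frame(replicate = integer(), sample_id = character(),
               line_id = character(), true = integer(), predicted = integer(),
               stringsAsFactors = FALSE)
  }
  structure(list(
    replicate_errors = errors,
    cv_error = mean(errors),
    pooled_error = nrow(ledger) / n_test_total,
    n_test_total = n_test_total,
    n_misclassified = nrow(ledger),
    misclassified_ledger = ledger,
    line_test_counts = line_counts,
    n_skipped = n_skipped,
    k = k, repeats = repeats, seed = rng_seed,
    mode = mode, h2_fixed = h2_fixed
  ), class = "cv_result")
}

make_stratified_folds <- function(y, k, rng_seed) {
  with_seed(rng_seed, {
    folds <- vector("list", k)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      assign_to <- rep(seq_len(k), length.out = length(idx))
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
    folds
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("repeated %d-fold CV, %d repeats (%d replicates, %d skipped)\n",
              x$k, x$repeats, length(x$replicate_errors), x$n_skipped))
  cat(sprintf("  CV error (mean of replicate ERs): %.6f (%.3f%%)\n",
              x$cv_error, 100 * x$cv_error))
  cat(sprintf("  pooled: %d misclassified of %d test observations (%.6f)\n",
              x$n_misclassified, x$n_test_total, x$pooled_error))
  invisible(x)
}

#' Per-line misclassification summary from a CV result
#'
#' @param result a [run_repeated_cv()] result
#' @return data.frame with per-line test appearances, misclassification counts
#'   and their ratio
#' @export
per_line_error_summary <- function(result) {
  stopifnot(inherits(result, "cv_result"))
  lines <- names(result$line_test_counts)
  mis <- table(factor(result$misclassified_ledger$line_id, levels = lines))
  data.frame(
    line_id = lines,
    n_tested = as.integer(result$line_test_counts),
    n_misclassified = as.integer(mis),
    error_rate = ifelse(result$line_test_counts > 0,
                        as.integer(mis) / as.integer(result$line_test_counts), 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write CV outputs: replicate-level TSV and a JSON summary
#' @param result a [run_repeated_cv()] result
#' @param dir output directory
#' @return invisibly, the directory
#' @export
write_cv_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(replicate = seq_along(result$replicate_errors),
               error_rate = result$replicate_errors),
    file.path(dir, "cv_replicates.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$misclassified_ledger,
                     file.path(dir, "cv_misclassified.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(cv_error = result$cv_error, pooled_error = result$pooled_error,
         n_misclassified = result$n_misclassified,
         n_test_total = result$n_test_total, n_skipped = result$n_skipped,
         k = result$k, repeats = result$repeats, seed = result$seed),
    file.path(dir, "cv_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
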