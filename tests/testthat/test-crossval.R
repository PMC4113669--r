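test_that("folds partition the samples into nearly equal random subsets", {
  folds <- make_folds(123, 5, rng_seed = 42)
  expect_equal(sort(unname(vapply(folds, length, integer(1)))), c(24L, 24L, 25L, 25L, 25L))
  expect_setequal(unlist(folds), 1:123)
  # leave-one-out limit
  loo <- make_folds(10, 10, rng_seed = 1)
  expect_true(all(vapply(loo, length, integer(1)) == 1L))
  # determinism under the seed; different seeds differ
  expect_identical(make_folds(50, 5, 7), make_folds(50, 5, 7))
  expect_false(identical(make_folds(50, 5, 7), make_folds(50, 5, 8)))
  expect_error(make_folds(4, 5, 1), "cannot exceed")
})

test_that("the test error rate is the misclassification fraction", {
  expect_equal(test_error_rate(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(test_error_rate(c(0, 1, 1), c(1, 1, 1)), 1 / 3)
  set.seed(9)
  a <- sample(0:1, 50, replace = TRUE)
  b <- sample(0:1, 50, replace = TRUE)
  cnt <- 0
  for (i in 1:50) if (a[i] != b[i]) cnt <- cnt + 1
  expect_equal(test_error_rate(a, b), cnt / 50)
  expect_error(test_error_rate(integer(0), integer(0)), "empty")
  expect_error(test_error_rate(c(0, 1), c(1)), "length")
})

test_that("repeated CV produces k x repeats replicates that partition each repeat", {
  sim <- simulate_dataset(sim_config(n_lines_high = 5, n_lines_low = 2,
                                     samples_per_line = 4, n_scaffolds = 8,
                                     n_snps = 50, missing_rate = 0,
                                     n_duplicate_samples = 0, seed = 33))
  panel <- sim$panel
  cv <- run_repeated_cv(panel, k = 4, repeats = 3, mode = "fixed_h2",
                        h2_fixed = 0.783, rng_seed = 5)
  expect_length(cv$replicate_errors, 12L)
  expect_equal(cv$n_test_total, 3L * nrow(panel$genotypes))
  expect_equal(cv$cv_error, mean(cv$replicate_errors))
  expect_equal(cv$n_misclassified, nrow(cv$misclassified_ledger))
  # every sample is tested exactly once per repeat
  expect_equal(sum(cv$line_test_counts), 3L * nrow(panel$genotypes))
  # pooled and replicate-average errors agree within the unequal-fold bound
  min_fold <- floor(nrow(panel$genotypes) / 4)
  expect_lt(abs(cv$pooled_error - cv$cv_error), 1 / min_fold)
  # determinism under the seed
  cv2 <- run_repeated_cv(panel, k = 4, repeats = 3, mode = "fixed_h2",
                         h2_fixed = 0.783, rng_seed = 5)
  expect_identical(cv$replicate_errors, cv2$replicate_errors)
})

test_that("a near-perfectly separable population is classified with near-zero error", {
  sim <- simulate_dataset(sim_config(seed = 1))
  qc <- qc_filter(sim$panel)
  cv <- run_repeated_cv(qc$panel, k = 5, repeats = 5, rng_seed = 11)
  expect_lt(cv$cv_error, 0.05)
  # all errors are accounted for in the ledger with their line ids
  expect_equal(nrow(cv$misclassified_ledger), cv$n_misclassified)
  expect_true(all(cv$misclassified_ledger$line_id %in% qc$panel$samples$line_id))
})

test_that("per-line summary matches a hand count on a constructed ledger", {
  ledger <- data.frame(
    replicate = c(1L, 2L, 7L),
    sample_id = c("S1", "S1", "S9"),
    line_id = c("LOW1", "LOW1", "HIGH2"),
    true = c(0L, 0L, 1L),
    predicted = c(1L, 1L, 0L),
    stringsAsFactors = FALSE
  )
  res <- structure(list(
    misclassified_ledger = ledger,
    line_test_counts = c(LOW1 = 40L, HIGH2 = 35L, HIGH1 = 35L)
  ), class = "cv_result")
  tab <- per_line_error_summary(res)
  expect_equal(tab$n_misclassified[tab$line_id == "LOW1"], 2L)
  expect_equal(tab$error_rate[tab$line_id == "LOW1"], 2 / 40)
  expect_equal(tab$n_misclassified[tab$line_id == "HIGH2"], 1L)
  expect_equal(tab$error_rate[tab$line_id == "HIGH1"], 0)
  # empty ledger -> all-zero table
  res0 <- structure(list(
    misclassified_ledger = ledger[0, ],
    line_test_counts = c(LOW1 = 10L, HIGH1 = 10L)
  ), class = "cv_result")
  tab0 <- per_line_error_summary(res0)
  expect_true(all(tab0$n_misclassified == 0L))
  expect_true(all(tab0$error_rate == 0))
})

test_that("single-class training folds are skipped and counted", {
  # 6 samples, only one of class 0: k = 2 puts the lone 0 in one fold, whose
  # complementary training fold is then single-class
  geno <- matrix(sample(0:2, 6 * 20, replace = TRUE), 6, 20)
  panel <- toy_panel(geno, vigor = c(0L, 1L, 1L, 1L, 1L, 1L),
                     line = rep(c("A", "B"), 3))
  suppressWarnings({
    cv <- run_repeated_cv(panel, k = 2, repeats = 2, mode = "fixed_h2",
                          h2_fixed = 0.5, rng_seed = 3)
  })
  expect_equal(cv$n_skipped + length(cv$replicate_errors), 4L)
  expect_gte(cv$n_skipped, 2L)
})

test_that("held-out low-line probabilities inflate monotonically as the fixed
           heritability is lowered (shrinkage toward the intercept)", {
  sim <- simulate_dataset(sim_config(seed = 5))
  qc <- qc_filter(sim$panel)
  panel <- qc$panel
  grm <- compute_grm(panel)
  y <- panel$samples$vigor_class
  test <- which(panel$samples$line_id == "LOW2")[1:3]
  ytr <- y
  ytr[test] <- NA
  p_by_h2 <- sapply(c(0.783, 0.5, 0.33, 0.2, 0.1, 0.05), function(h2) {
    fit <- fit_threshold_model(ytr, grm, mode = "fixed_h2", h2_fixed = h2)
    mean(classify(fit, panel$samples$sample_id[test])$p_high)
  })
  expect_true(all(diff(p_by_h2) > 0))
})

test_that("CV outputs are written as replicate TSV plus JSON summary", {
  sim <- simulate_dataset(sim_config(n_lines_high = 4, n_lines_low = 2,
                                     samples_per_line = 3, n_scaffolds = 5,
                                     n_snps = 30, missing_rate = 0,
                                     n_duplicate_samples = 0, seed = 12))
  cv <- run_repeated_cv(sim$panel, k = 3, repeats = 2, mode = "fixed_h2",
                        h2_fixed = 0.7, rng_seed = 2)
  dir <- withr::local_tempdir()
  write_cv_result(cv, dir)
  reps <- read.delim(file.path(dir, "cv_replicates.tsv"))
  expect_equal(reps$error_rate, cv$replicate_errors)
  js <- jsonlite::read_json(file.path(dir, "cv_summary.json"))
  expect_equal(js$cv_error, cv$cv_error, tolerance = 1e-12)
  expect_equal(js$n_test_total, cv$n_test_total)
})
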