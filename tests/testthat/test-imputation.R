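test_that("a duplicated scaffold-mate (r2 = 1) determines the imputed value", {
  set.seed(5)
  base <- sample(0:2, 30, replace = TRUE)
  geno <- cbind(base, base, sample(0:2, 30, replace = TRUE))
  geno[7, 1] <- NA
  panel <- toy_panel(geno, scaffold = c("scA", "scA", "scB"))
  imp <- impute_missing(panel)
  expect_equal(imp$genotypes[7, 1], base[7])
  expect_equal(attr(imp, "imputed_cells")$method, "ld_regression")
})

test_that("markers without informative neighbors fall back to the mode", {
  geno <- cbind(c(0L, 0L, 0L, 2L, NA),
                c(1L, 0L, 2L, 1L, 0L))
  panel <- toy_panel(geno, scaffold = c("scA", "scB"))
  imp <- impute_missing(panel)
  expect_equal(imp$genotypes[5, 1], 0L)
  expect_equal(attr(imp, "imputed_cells")$method, "mode")
})

test_that("imputation never alters non-missing cells and fills everything", {
  sim <- simulate_dataset(block_ld_config(71))
  masked <- inject_missing(sim$panel, 0.05, seed = 2)
  imp <- impute_missing(masked)
  obs <- !is.na(masked$genotypes)
  expect_identical(imp$genotypes[obs], masked$genotypes[obs])
  expect_false(anyNA(imp$genotypes))
  expect_true(all(imp$genotypes %in% 0:2))
  # entirely missing marker errors by name
  geno <- cbind(c(NA, NA, NA), c(0L, 1L, 2L))
  expect_error(impute_missing(toy_panel(geno)), "M1")
})

test_that("rounding of regression predictions resolves ties toward the heterozygote", {
  expect_equal(vigorclass:::round_genotype(0.5), 1L)
  expect_equal(vigorclass:::round_genotype(1.5), 1L)
  expect_equal(vigorclass:::round_genotype(0.4), 0L)
  expect_equal(vigorclass:::round_genotype(1.8), 2L)
  expect_equal(vigorclass:::round_genotype(-3), 0L)
  expect_equal(vigorclass:::round_genotype(7), 2L)
})

test_that("masking draws the requested number of cells, reproducibly", {
  geno <- matrix(sample(0:2, 100, replace = TRUE), 10, 10)
  panel <- toy_panel(geno)
  mk <- mask_genotypes(panel, 0.2, rng_seed = 4)
  expect_equal(nrow(mk$mask), 20L)
  expect_equal(sum(is.na(mk$panel$genotypes)), 20L)
  mk2 <- mask_genotypes(panel, 0.2, rng_seed = 4)
  expect_identical(mk$mask, mk2$mask)
  # single-cell mask
  mk1 <- mask_genotypes(panel, 0.011, rng_seed = 1)
  expect_equal(nrow(mk1$mask), 1L)
  expect_error(mask_genotypes(panel, 0, rng_seed = 1), "\\(0, 1\\)")
  expect_error(mask_genotypes(mk$panel, 0.1, rng_seed = 1), "complete")
})

test_that("the masking experiment scores only masked cells and supports
           replacement imputers", {
  panel <- simulate_dataset(block_ld_config(81, n_lines_high = 5, n_lines_low = 2,
                                            samples_per_line = 4, n_snps = 60,
                                            n_scaffolds = 6))$panel
  # oracle imputer: returns the truth -> accuracy exactly 1
  oracle <- function(masked) panel
  exp_oracle <- accuracy_experiment(panel, fractions = c(0.02, 0.05),
                                    replicates = 2, rng_seed = 3,
                                    imputer = oracle)
  expect_equal(exp_oracle$accuracies, c(1, 1))
  # random imputer drawing from marker genotype frequencies: expected accuracy
  # is the frequency-weighted self-match rate sum_g f_g^2, averaged over cells
  rand_imputer <- function(masked) {
    geno <- masked$genotypes
    for (j in which(colSums(is.na(geno)) > 0)) {
      obs <- geno[!is.na(geno[, j]), j]
      geno[is.na(geno[, j]), j] <- sample(obs, sum(is.na(geno[, j])), replace = TRUE)
    }
    genotype_panel(geno, masked$markers[, c("marker_id", "chromosome", "scaffold_id", "position_bp")],
                   masked$samples[, c("sample_id", "line_id", "vigor_class")])
  }
  set.seed(11)
  exp_rand <- accuracy_experiment(panel, fractions = 0.10, replicates = 20,
                                  rng_seed = 5, imputer = rand_imputer)
  f <- apply(panel$genotypes, 2, function(g) sum(table(g)^2) / length(g)^2)
  expect_equal(exp_rand$accuracies, mean(f), tolerance = 0.05)
})

test_that("accuracy degrades with the masking fraction on block-LD data", {
  panel <- simulate_dataset(block_ld_config(91))$panel
  exp <- accuracy_experiment(panel, fractions = c(0.01, 0.05, 0.20),
                             replicates = 3, rng_seed = 7)
  expect_true(all(diff(exp$accuracies) <= 0.02))  # flat-then-drop within noise
  expect_gt(exp$accuracies[1], exp$accuracies[3])
  expect_equal(nrow(exp$per_replicate), 9L)
})

test_that("the empirical accuracy curve interpolates linearly", {
  exp <- structure(list(
    fractions = c(0.01, 0.02, 0.03, 0.05, 0.10, 0.20),
    accuracies = c(0.8405, 0.8402, 0.8402, 0.8396, 0.8301, 0.8089),
    replicates_per_fraction = 5L, per_replicate = NULL, seed = 1L
  ), class = "masking_experiment")
  # querying a measured fraction returns its mean exactly
  expect_equal(interpolate_accuracy(exp, 0.05), 0.8396)
  # between 3% and 5% the curve is linear: frozen expected value computed as
  # 0.8402 + (0.0314 - 0.03)/(0.05 - 0.03) * (0.8396 - 0.8402)
  expect_equal(round(interpolate_accuracy(exp, 0.0314), 5), 0.84016)
  expect_error(interpolate_accuracy(exp, 0.005), "extrapolation")
  expect_error(interpolate_accuracy(exp, 0.3), "extrapolation")
  simple <- structure(list(fractions = c(0.01, 0.02), accuracies = c(1.0, 0.9),
                           replicates_per_fraction = 1L, per_replicate = NULL,
                           seed = 1L), class = "masking_experiment")
  expect_equal(interpolate_accuracy(simple, 0.015), 0.95)
})

test_that("the LD imputer beats the modal baseline at 3% masking on block-LD data", {
  wins <- 0
  for (s in 1:10) {
    panel <- simulate_dataset(block_ld_config(200 + s))$panel
    mk <- mask_genotypes(panel, 0.03, rng_seed = s)
    truth <- panel$genotypes[mk$mask]
    a_ld <- mean(impute_missing(mk$panel)$genotypes[mk$mask] == truth)
    a_mode <- mean(modal_imputer(mk$panel)$genotypes[mk$mask] == truth)
    wins <- wins + (a_ld > a_mode)
  }
  expect_gte(wins, 9)
})

test_that("with mutually independent markers the LD imputer reduces to the
           modal baseline", {
  set.seed(15)
  geno <- matrix(sample(0:2, 120 * 40, replace = TRUE,
                        prob = c(0.5, 0.3, 0.2)), 120, 40)
  panel <- toy_panel(geno, scaffold = rep(paste0("sc", 1:4), each = 10))
  mk <- mask_genotypes(panel, 0.03, rng_seed = 8)
  truth <- panel$genotypes[mk$mask]
  a_ld <- mean(impute_missing(mk$panel)$genotypes[mk$mask] == truth)
  a_mode <- mean(modal_imputer(mk$panel)$genotypes[mk$mask] == truth)
  expect_lt(abs(a_ld - a_mode), 0.12)
})
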