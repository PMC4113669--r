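test_that("heritability and its inverse follow the liability formula", {
  c0 <- pi^2 / 3
  expect_equal(heritability(0), 0)
  expect_equal(heritability(c0), 0.5)
  expect_equal(variance_from_h2(0), 0)
  expect_equal(variance_from_h2(0.5), c0)
  expect_equal(round(variance_from_h2(0.2), 4), 0.8225)
  # round trip is the identity on [0, 0.99]
  grid <- seq(0, 0.99, by = 0.01)
  expect_equal(heritability(variance_from_h2(grid)), grid, tolerance = 1e-12)
  expect_error(heritability(-1), "non-negative")
  expect_error(variance_from_h2(1), "\\[0, 1\\)")
})

test_that("classification applies the logistic CDF with ties going low", {
  g <- stats::setNames(c(-0.3, 0, 20), paste0("S", 1:3))
  fit <- structure(list(mu = 0.3, g = g), class = "liability_fit")
  out <- classify(fit)
  # closed-form logistic CDF at mu + g
  expect_equal(out$p_high, exp(0.3 + g) / (1 + exp(0.3 + g)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(out$predicted_class, c(0L, 1L, 1L))  # p = 0.5 -> class 0
  set.seed(4)
  eta <- rnorm(100, sd = 3)
  fit2 <- structure(list(mu = 0, g = stats::setNames(eta, paste0("T", 1:100))),
                    class = "liability_fit")
  expect_equal(classify(fit2)$p_high, plogis(eta), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(classify(fit, "nope"), "unknown sample")
})

test_that("with an identity GRM and random labels the fit collapses to the intercept", {
  set.seed(42)
  G <- diag(40)
  dimnames(G) <- list(paste0("s", 1:40), paste0("s", 1:40))
  y <- rep(c(0L, 1L), 20)
  fit <- fit_threshold_model(y, G, se_h2 = FALSE)
  expect_lt(fit$sigma_a2, 0.01)
  expect_equal(fit$mu, qlogis(mean(y)), tolerance = 1e-6)
  expect_true(all(abs(fit$g) < 1e-6))
  expect_equal(fit$deviance, fit$null_deviance, tolerance = 1e-6)
})

test_that("Laplace marginal likelihood agrees with 3-dim quadrature where the
           approximation is exact enough, and with an independent Laplace everywhere", {
  G <- matrix(c(1.2, 0.5, 0.2,
                0.5, 1.1, 0.4,
                0.2, 0.4, 1.3), 3, 3)
  y <- c(1, 0, 1)
  for (s2 in c(0.05, 0.1)) {
    la <- vigorclass:::laplace_marginal_loglik(y, G, s2, mu = 0.4)
    qu <- quadrature_marginal_loglik(y, G, s2, mu = 0.4)
    expect_lt(abs(la - qu), 1e-3)
  }
  # at larger variances the Laplace approximation departs from the exact
  # integral, but must still match an independently coded Laplace exactly
  gaps <- sapply(c(0.2, 0.5, 2, 8), function(s2) {
    la <- vigorclass:::laplace_marginal_loglik(y, G, s2, mu = 0.4)
    expect_equal(la, laplace_gspace(y, G, s2, 0.4), tolerance = 1e-8)
    abs(la - quadrature_marginal_loglik(y, G, s2, mu = 0.4))
  })
  # the approximation error shrinks monotonically as sigma_a2 -> 0
  expect_true(all(diff(gaps) > 0))
})

test_that("G-BLUP genetic values equal ridge-logistic RR-BLUP marker-effect sums", {
  sim <- simulate_dataset(sim_config(n_lines_high = 5, n_lines_low = 2,
                                     samples_per_line = 4, n_scaffolds = 10,
                                     n_snps = 60, missing_rate = 0,
                                     n_duplicate_samples = 0, seed = 8))
  panel <- sim$panel
  y <- panel$samples$vigor_class
  grm <- compute_grm(panel)
  for (s2 in c(0.5, 3)) {
    fit <- fit_threshold_model(y, grm, mode = "fixed_h2",
                               h2_fixed = s2 / (s2 + pi^2 / 3))
    rr <- rr_blup_logistic(panel, y, s2)
    expect_equal(unname(fit$g), rr$g, tolerance = 1e-6)
    expect_equal(fit$mu, rr$mu, tolerance = 1e-6)
  }
})

test_that("unphenotyped samples get genetic values through the joint prior", {
  sim <- simulate_dataset(sim_config(n_lines_high = 5, n_lines_low = 2,
                                     samples_per_line = 5, n_scaffolds = 8,
                                     n_snps = 60, missing_rate = 0,
                                     n_duplicate_samples = 0, seed = 13))
  panel <- sim$panel
  y <- panel$samples$vigor_class
  y_mask <- y
  test_idx <- c(3, 11, 30)
  y_mask[test_idx] <- NA
  fit <- fit_threshold_model(y_mask, compute_grm(panel), mode = "fixed_h2",
                             h2_fixed = 0.783)
  expect_equal(length(fit$g), nrow(panel$genotypes))
  # held-out samples inherit the genetic value of their (near-clone) line
  for (i in test_idx) {
    mates <- setdiff(which(panel$samples$line_id == panel$samples$line_id[i]),
                     i)
    expect_equal(unname(fit$g[i]), mean(fit$g[mates]), tolerance = 0.35)
  }
  expect_equal(fit$n_obs, nrow(panel$genotypes) - 3L)
})

test_that("fixed-h2 mode sets the variance through the inverse liability formula", {
  sim <- simulate_dataset(sim_config(n_lines_high = 4, n_lines_low = 2,
                                     samples_per_line = 4, n_scaffolds = 6,
                                     n_snps = 40, missing_rate = 0,
                                     n_duplicate_samples = 0, seed = 3))
  grm <- compute_grm(sim$panel)
  y <- sim$panel$samples$vigor_class
  fit <- fit_threshold_model(y, grm, mode = "fixed_h2", h2_fixed = 0.33)
  expect_equal(fit$sigma_a2, variance_from_h2(0.33))
  expect_equal(fit$h2, 0.33)
  expect_equal(fit$fixed_h2, 0.33)
  expect_error(fit_threshold_model(y, grm, mode = "fixed_h2", h2_fixed = 1.2),
               "\\(0, 1\\)")
  expect_error(fit_threshold_model(rep(1L, length(y)), grm), "each class")
})

test_that("training labels are reproduced perfectly at high fixed variance on
           separable line-structured data", {
  panel <- complete_studylike(21)
  # line-consensus labels: perfectly separable by line genotype
  y <- as.integer(startsWith(panel$samples$line_id, "HIGH"))
  grm <- compute_grm(panel)
  fit_hi <- fit_threshold_model(y, grm, mode = "fixed_h2", h2_fixed = 0.99)
  pred <- classify(fit_hi, panel$samples$sample_id)$predicted_class
  expect_equal(test_error_rate(y, pred), 0)
  # penalized fit to training labels never degrades as the variance grows
  devs <- sapply(c(0.3, 0.6, 0.9, 0.99), function(h2) {
    f <- fit_threshold_model(y, grm, mode = "fixed_h2", h2_fixed = h2)
    p <- classify(f, panel$samples$sample_id)$p_high
    -2 * sum(y * log(p) + (1 - y) * log(1 - p))  # training Bernoulli deviance
  })
  expect_true(all(diff(devs) < 1e-8))
})

test_that("the boundary-corrected LRT uses the chi-square mixture", {
  fit0 <- structure(list(deviance = 100, null_deviance = 100, fixed_h2 = NULL),
                    class = "liability_fit")
  expect_equal(likelihood_ratio_test(fit0)$p_value, 0.5)
  fit1 <- structure(list(deviance = 100, null_deviance = 102.706, fixed_h2 = NULL),
                    class = "liability_fit")
  # mixture quantile: 0.5 * P(chi2_1 > 2.706) = 0.05
  expect_equal(likelihood_ratio_test(fit1)$p_value, 0.05, tolerance = 1e-3)
  fit_bad <- structure(list(deviance = 103, null_deviance = 100, fixed_h2 = NULL),
                       class = "liability_fit")
  expect_error(likelihood_ratio_test(fit_bad), "converge")
  fit_fixed <- structure(list(deviance = 90, null_deviance = 100, fixed_h2 = 0.5),
                         class = "liability_fit")
  expect_error(likelihood_ratio_test(fit_fixed), "estimated")
})

test_that("the h2 standard error follows the delta method on the profile curvature", {
  sim <- simulate_dataset(sim_config(n_lines_high = 6, n_lines_low = 2,
                                     samples_per_line = 5, n_scaffolds = 10,
                                     n_snps = 80, missing_rate = 0,
                                     n_duplicate_samples = 0, seed = 19))
  grm <- compute_grm(sim$panel)
  y <- sim$panel$samples$vigor_class
  fit <- fit_threshold_model(y, grm)
  expect_true(is.finite(fit$h2_se) && fit$h2_se > 0)
  # recompute the curvature independently
  decomp <- vigorclass:::grm_decomp(grm)
  s2 <- fit$sigma_a2
  h <- max(1e-3, 1e-3 * s2)
  ll <- function(s) vigorclass:::laplace_fit_inner(y, decomp, s)$loglik
  curv <- (ll(s2 + h) - 2 * ll(s2) + ll(max(s2 - h, 1e-8))) / h^2
  se_sigma <- sqrt(-1 / curv)
  cst <- pi^2 / 3
  expect_equal(fit$h2_se, cst / (s2 + cst)^2 * se_sigma, tolerance = 1e-6)
})

test_that("fit summary writer produces the per-sample table and run metadata", {
  sim <- simulate_dataset(sim_config(n_lines_high = 4, n_lines_low = 2,
                                     samples_per_line = 3, n_scaffolds = 5,
                                     n_snps = 30, missing_rate = 0,
                                     n_duplicate_samples = 0, seed = 2))
  fit <- fit_threshold_model(sim$panel$samples$vigor_class,
                             compute_grm(sim$panel), se_h2 = FALSE)
  path <- file.path(withr::local_tempdir(), "fit.tsv")
  write_fit_summary(fit, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), nrow(sim$panel$genotypes))
  expect_named(tab, c("sample_id", "g", "p_high", "predicted_class"))
  meta <- yaml::read_yaml(paste0(path, ".summary.yaml"))
  expect_equal(meta$h2, fit$h2, tolerance = 1e-6)
})
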