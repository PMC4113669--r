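#' Liability-scale heritability from the genetic variance
#'
#' For a threshold model with logistic residuals (scale s = 1, variance
#' \eqn{\pi^2/3}), narrow-sense heritability on the liability scale is
#' \deqn{h^2 = \sigma_a^2 / (\sigma_a^2 + \pi^2/3).}
#' The constant \eqn{\pi^2/3 \approx 3.29} is used at full precision.
#'
#' @param sigma_a2 additive genetic variance on the liability scale (>= 0)
#' @return heritability in [0, 1)
#' @export
heritability <- function(sigma_a2) {
  if (any(!is.finite(sigma_a2)) || any(sigma_a2 < 0)) {
    stop("sigma_a2 must be finite and non-negative")
  }
  sigma_a2 / (sigma_a2 + logistic_variance())
}

#' Genetic variance implied by a liability-scale heritability
#'
#' Inverse of [heritability()]: \eqn{\sigma_a^2 = h^2/(1-h^2) \cdot \pi^2/3}.
#' Used to fix the covariance structure when running the model at an imposed
#' (rather than estimated) heritability.
#'
#' @param h2 heritability in [0, 1)
#' @return genetic variance on the liability scale
#' @export
variance_from_h2 <- function(h2) {
  if (any(!is.finite(h2)) || any(h2 < 0) || any(h2 >= 1)) {
    stop("h2 must lie in [0, 1)")
  }
  h2 / (1 - h2) * logistic_variance()
}

# -- internal machinery -------------------------------------------------------

# Decompose a GRM once so repeated fits (cross-validation) can reuse it.
# g is reparameterized as g = sqrt(sigma_a2) * L v with v ~ N(0, I_r) and
# L = U diag(sqrt(lambda_+)) from the eigendecomposition of G; negative
# eigenvalues (numerical noise or true rank deficiency from duplicated lines)
# are clamped to zero and their columns dropped. K = G sigma_a2 is therefore
# never inverted and needs no ridge.
grm_decomp <- function(grm) {
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  eg <- eigen(G, symmetric = TRUE)
  lam <- eg$values
  tol <- max(lam) * 1e-12
  keep <- lam > tol
  if (!any(keep)) stop("G has no positive eigenvalues")
  list(L0 = eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam[keep]), sum(keep)),
       rank = sum(keep),
       ids = if (inherits(grm, "grm")) grm$sample_ids else rownames(G),
       min_eig = min(lam), max_eig = max(lam))
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  small <- x <= 30
  out[small] <- log1p(exp(x[small]))
  out[!small] <- x[!small] + exp(-x[!small])
  out
}

# Penalized (joint) log-likelihood and Newton mode for (mu, v) given sigma2.
# y: 0/1 with NA for unphenotyped; only phenotyped entries carry records.
# Returns the Laplace-approximate marginal log-likelihood and the mode.
laplace_fit_inner <- function(y, decomp, sigma2, mu_fixed = NULL,
                              tol = 1e-8, max_iter = 200L) {
  obs <- which(!is.na(y))
  yo <- y[obs]
  L <- sqrt(sigma2) * decomp$L0
  r <- ncol(L)
  Lo <- L[obs, , drop = FALSE]
  est_mu <- is.null(mu_fixed)
  mu <- if (est_mu) stats::qlogis(min(max(mean(yo), 1e-3), 1 - 1e-3)) else mu_fixed
  v <- numeric(r)

  pen_ll <- function(mu, v) {
    eta <- mu + as.numeric(Lo %*% v)
    sum(yo * eta - log1pexp(eta)) - 0.5 * sum(v^2)
  }
  cur <- pen_ll(mu, v)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- mu + as.numeric(Lo %*% v)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    res <- yo - p
    g_v <- as.numeric(crossprod(Lo, res)) - v
    if (est_mu) {
      g_mu <- sum(res)
      grad <- c(g_mu, g_v)
      LtW <- Lo * w                       # rows scaled by w
      H <- matrix(0, r + 1L, r + 1L)
      H[1L, 1L] <- sum(w)
      H[1L, -1L] <- H[-1L, 1L] <- colSums(LtW)
      H[-1L, -1L] <- crossprod(Lo, LtW) + diag(r)
    } else {
      grad <- g_v
      H <- crossprod(Lo, Lo * w) + diag(r)
    }
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H)))
    # backtracking line search on the penalized log-likelihood
    alpha <- 1
    repeat {
      if (est_mu) {
        mu_new <- mu + alpha * step[1L]
        v_new <- v + alpha * step[-1L]
      } else {
        mu_new <- mu
        v_new <- v + alpha * step
      }
      new <- pen_ll(mu_new, v_new)
      if (new >= cur - 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    if (new < cur + 1e-12 && sqrt(sum(grad^2)) < 1e-6) {
      mu <- mu_new; v <- v_new; cur <- new
      converged <- TRUE
      break
    }
    mu <- mu_new; v <- v_new; cur <- new
  }

  # Laplace correction: -1/2 log det(I_r + Lo' W Lo)  (Sylvester: equals
  # log det(I + W^{1/2} K W^{1/2}) with K = sigma2 G)
  eta <- mu + as.numeric(Lo %*% v)
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  A <- crossprod(Lo, Lo * w) + diag(r)
  ld <- as.numeric(determinant(A, logarithm = TRUE)$modulus)
  loglik <- sum(yo * eta - log1pexp(eta)) - 0.5 * sum(v^2) - 0.5 * ld

  g <- as.numeric(L %*% v)
  names(g) <- decomp$ids
  list(loglik = loglik, mu = mu, v = v, g = g, converged = converged,
       iterations = it)
}

# Laplace-approximate marginal log-likelihood at a given sigma2 (mu profiled
# out by joint maximization). Exposed internally for the quadrature oracle.
laplace_marginal_loglik <- function(y, grm, sigma2, mu = NULL) {
  decomp <- if (is.list(grm) && !is.null(grm$L0)) grm else grm_decomp(grm)
  laplace_fit_inner(y, decomp, sigma2, mu_fixed = mu)$loglik
}

# -- public fitting interface -------------------------------------------------

#' Fit the liability-threshold G-BLUP model
#'
#' Fits the binary-trait threshold model
#' \deqn{l = 1\mu + X g + e, \quad g \sim N(0, G\sigma_a^2), \quad
#'       e \sim \mathrm{Logistic}(0, s = 1)}
#' by Laplace-approximate maximum marginal likelihood: an inner Newton
#' optimization of the penalized logistic log-likelihood for \eqn{(\mu, g)}
#' given \eqn{\sigma_a^2}, and an outer Brent search for \eqn{\sigma_a^2} on
#' the log scale over \eqn{[10^{-6}, 10^4]}. The design matrix X maps records
#' to the genetic values of phenotyped samples; unphenotyped samples carry no
#' records but receive genetic values through the joint prior, which is how
#' test-set individuals are predicted.
#'
#' In `mode = "fixed_h2"` the variance is set to
#' \eqn{\sigma_a^2 = h^2/(1-h^2)\,\pi^2/3} and only \eqn{(\mu, g)} are
#' estimated (the sensitivity analysis at artificially lowered heritability).
#'
#' @param y binary phenotype vector (0 = low, 1 = high), NA for unphenotyped,
#'   aligned with the GRM sample order
#' @param grm a [compute_grm()] result (or a bare symmetric matrix)
#' @param mode `"estimate"` (maximize over \eqn{\sigma_a^2}) or `"fixed_h2"`
#' @param h2_fixed heritability in (0, 1), required when `mode = "fixed_h2"`
#' @param se_h2 compute a delta-method standard error for \eqn{h^2} from the
#'   numerical curvature of the profile log-likelihood (default TRUE in
#'   estimate mode)
#' @return an object of class `liability_fit`: `mu`, `g` (named, one entry per
#'   GRM sample), `sigma_a2`, `h2`, `h2_se`, `deviance` (-2 x Laplace marginal
#'   log-likelihood), `null_deviance` (intercept-only), `converged`,
#'   `fixed_h2`, `n_obs`
#' @export
fit_threshold_model <- function(y, grm, mode = c("estimate", "fixed_h2"),
                                h2_fixed = NULL, se_h2 = TRUE) {
  mode <- match.arg(mode)
  decomp <- if (is.list(grm) && !is.null(grm$L0)) grm else grm_decomp(grm)
  n <- length(decomp$ids)
  if (length(y) != n) stop("phenotype vector length must match the GRM (", n, ")")
  obs <- which(!is.na(y))
  if (length(unique(y[obs])) < 2L) {
    stop("need at least one phenotyped sample of each class")
  }
  if (!all(y[obs] %in% 0:1)) stop("phenotypes must be coded 0/1")

  # intercept-only null model (the sigma_a2 -> 0 limit)
  p0 <- mean(y[obs])
  null_dev <- -2 * sum(y[obs] * log(p0) + (1 - y[obs]) * log(1 - p0))

  lower <- log(1e-6); upper <- log(1e4)
  if (mode == "fixed_h2") {
    if (is.null(h2_fixed) || h2_fixed <= 0 || h2_fixed >= 1) {
      stop("mode 'fixed_h2' requires h2_fixed in (0, 1)")
    }
    sigma2 <- variance_from_h2(h2_fixed)
    fit <- laplace_fit_inner(y, decomp, sigma2)
    converged <- fit$converged
    h2_se_val <- NA_real_
  } else {
    objective <- function(ls) laplace_fit_inner(y, decomp, exp(ls))$loglik
    opt <- stats::optimize(objective, c(lower, upper), maximum = TRUE, tol = 1e-6)
    sigma2 <- exp(opt$maximum)
    fit <- laplace_fit_inner(y, decomp, sigma2)
    at_upper <- opt$maximum > upper - 1e-3
    if (at_upper) {
      warning("sigma_a2 search hit its upper bound (1e4): quasi-separation; ",
              "estimate reported at the bound")
    }
    converged <- fit$converged && !at_upper
    # sigma_a2 = 0 lies on the closed parameter boundary, where the marginal
    # likelihood is exactly the intercept-only likelihood; Brent cannot land
    # on an endpoint, so collapse to the null model when it fits at least as
    # well as the interior optimum
    ll0 <- -null_dev / 2
    at_lower <- ll0 >= fit$loglik
    if (at_lower) {
      sigma2 <- 0
      p0c <- min(max(mean(y[obs]), 1e-12), 1 - 1e-12)
      fit <- list(loglik = ll0, mu = stats::qlogis(p0c),
                  g = stats::setNames(numeric(n), decomp$ids),
                  converged = TRUE, iterations = 0L)
    }
    h2_se_val <- NA_real_
    if (se_h2 && !at_lower) {
      h <- max(1e-3, 1e-3 * sigma2)
      llp <- laplace_fit_inner(y, decomp, sigma2 + h)$loglik
      llm <- laplace_fit_inner(y, decomp, max(sigma2 - h, 1e-8))$loglik
      curv <- (llp - 2 * fit$loglik + llm) / h^2
      if (is.finite(curv) && curv < 0) {
        se_sigma <- sqrt(-1 / curv)
        cst <- logistic_variance()
        h2_se_val <- cst / (sigma2 + cst)^2 * se_sigma
      }
    }
  }

  structure(list(
    mu = fit$mu,
    g = fit$g,
    sigma_a2 = sigma2,
    h2 = heritability(sigma2),
    h2_se = h2_se_val,
    deviance = -2 * fit$loglik,
    null_deviance = null_dev,
    converged = converged,
    fixed_h2 = if (mode == "fixed_h2") h2_fixed else NULL,
    n_obs = length(obs),
    inner_iterations = fit$iterations
  ), class = "liability_fit")
}

#' @export
print.liability_fit <- function(x, ...) {
  cat("liability-threshold G-BLUP fit\n")
  cat(sprintf("  n phenotyped: %d | mu = %.4f\n", x$n_obs, x$mu))
  if (is.null(x$fixed_h2)) {
    cat(sprintf("  sigma_a2 = %.4f  h2 = %.3f (SE %.3f)\n",
                x$sigma_a2, x$h2, x$h2_se))
  } else {
    cat(sprintf("  sigma_a2 fixed at %.4f (h2 = %.3f)\n", x$sigma_a2, x$fixed_h2))
  }
  cat(sprintf("  deviance %.3f (null %.3f) | converged: %s\n",
              x$deviance, x$null_deviance, x$converged))
  invisible(x)
}

#' Class probabilities and predicted classes from a fitted threshold model
#'
#' The probability of high vigor is the logistic CDF at the fitted liability:
#' \eqn{p_i = e^{\mu + g_i} / (1 + e^{\mu + g_i})}. A sample is classified
#' high (1) iff \eqn{p_i > 0.5}; ties at exactly 0.5 go to the low class, per
#' the "> / <= 0.5" rule.
#'
#' @param fit a [fit_threshold_model()] result
#' @param sample_ids samples to classify (default: all samples in the fit)
#' @return data.frame with `sample_id`, `p_high`, `predicted_class`
#' @export
classify <- function(fit, sample_ids = NULL) {
  stopifnot(inherits(fit, "liability_fit"))
  if (is.null(sample_ids)) sample_ids <- names(fit$g)
  unknown <- setdiff(sample_ids, names(fit$g))
  if (length(unknown)) {
    stop("unknown sample id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  p <- stats::plogis(fit$mu + fit$g[sample_ids])
  data.frame(sample_id = sample_ids,
             p_high = as.numeric(p),
             predicted_class = as.integer(p > 0.5),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Likelihood ratio test of the genomic model against the intercept-only null
#'
#' Compares the full threshold model with the intercept-only model. Because
#' \eqn{\sigma_a^2 = 0} sits on the boundary of its parameter space, the null
#' distribution of the deviance drop is the 50:50 mixture of \eqn{\chi^2_0}
#' and \eqn{\chi^2_1}: \eqn{p = 0.5\,P(\chi^2_1 > \mathrm{stat})} for a
#' positive statistic, and \eqn{p = 0.5} at zero.
#'
#' @param fit a [fit_threshold_model()] result with \eqn{\sigma_a^2} estimated
#' @param tol negative statistics smaller than `-tol` raise a convergence error
#' @return list with `statistic`, `df` (boundary mixture), `p_value`
#' @export
likelihood_ratio_test <- function(fit, tol = 1e-6) {
  stopifnot(inherits(fit, "liability_fit"))
  if (!is.null(fit$fixed_h2)) {
    stop("LRT requires sigma_a2 to have been estimated, not fixed")
  }
  stat <- fit$null_deviance - fit$deviance
  if (stat < -tol) {
    stop("negative LRT statistic (", signif(stat, 4),
         "): variance optimization did not converge")
  }
  stat <- max(stat, 0)
  p <- if (stat == 0) 0.5 else 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, df = "0.5*chi2_0 + 0.5*chi2_1", p_value = p)
}

#' Write a fit summary: per-sample TSV plus a YAML run summary
#'
#' @param fit a [fit_threshold_model()] result
#' @param path output TSV path (`sample_id`, `g`, `p_high`, `predicted_class`);
#'   the run summary goes to `<path>.summary.yaml`
#' @return invisibly, `path`
#' @export
write_fit_summary <- function(fit, path) {
  cls <- classify(fit)
  cls$g <- as.numeric(fit$g[cls$sample_id])
  utils::write.table(cls[, c("sample_id", "g", "p_high", "predicted_class")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(mu = fit$mu, sigma_a2 = fit$sigma_a2, h2 = fit$h2,
                        h2_se = fit$h2_se, deviance = fit$deviance,
                        null_deviance = fit$null_deviance,
                        converged = fit$converged,
                        fixed_h2 = fit$fixed_h2, n_obs = fit$n_obs),
                   paste0(path, ".summary.yaml"))
  invisible(path)
}
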