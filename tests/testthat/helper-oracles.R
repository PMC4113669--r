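# Independent oracles used across the suite. Everything here is deliberately
# naive (loops, quadrature, textbook IRLS) and shares no code with the package
# internals it checks.

# Gauss-Hermite nodes/weights by Golub-Welsch (eigenvalues of the Jacobi
# matrix); weight function exp(-x^2)
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Exact (to quadrature accuracy) marginal log-likelihood of the 3-sample
# Bernoulli-logit model with g ~ N(0, sigma2 * G), by 3-dimensional product
# Gauss-Hermite integration
quadrature_marginal_loglik <- function(y, G, sigma2, mu, n_nodes = 40) {
  stopifnot(length(y) == 3L)
  gh <- gauss_hermite(n_nodes)
  L <- t(chol(sigma2 * G))
  w <- gh$weights / sqrt(pi)
  total <- 0
  for (a in seq_len(n_nodes)) for (b in seq_len(n_nodes)) for (cc in seq_len(n_nodes)) {
    u <- sqrt(2) * c(gh$nodes[a], gh$nodes[b], gh$nodes[cc])
    eta <- mu + as.numeric(L %*% u)
    total <- total + w[a] * w[b] * w[cc] *
      prod(stats::plogis(eta)^y * (1 - stats::plogis(eta))^(1 - y))
  }
  log(total)
}

# Independent Laplace implementation: direct g-space Newton with an explicit
# K^{-1}, no reparameterization (requires positive-definite G)
laplace_gspace <- function(y, G, sigma2, mu) {
  K <- sigma2 * G
  Kinv <- solve(K)
  n <- length(y)
  g <- rep(0, n)
  for (it in 1:200) {
    p <- stats::plogis(mu + g)
    w <- pmax(p * (1 - p), 1e-12)
    grad <- (y - p) - as.numeric(Kinv %*% g)
    g <- g + solve(diag(w) + Kinv, grad)
    if (sqrt(sum(grad^2)) < 1e-11) break
  }
  p <- stats::plogis(mu + g)
  w <- pmax(p * (1 - p), 1e-12)
  eta <- mu + g
  as.numeric(sum(y * eta - log1p(exp(eta))) - 0.5 * sum(g * (Kinv %*% g)) -
    0.5 * determinant(diag(n) + K %*% diag(w, n), logarithm = TRUE)$modulus)
}

# Ridge-penalized logistic regression on centered marker dosages (RR-BLUP with
# Bernoulli-logit likelihood), Newton until gradient ~ 0. The prior on marker
# effects a is N(0, I sigma2 / d) with d = 2 * sum p(1-p), so that
# Var(Z a) = G sigma2 -- the marker-effect parameterization of G-BLUP.
rr_blup_logistic <- function(panel, y, sigma2) {
  geno <- panel$genotypes
  p <- colMeans(geno) / 2
  poly <- p > 0 & p < 1
  Z <- sweep(geno, 2, 2 * p, `-`)[, poly, drop = FALSE]
  d <- 2 * sum(p[poly] * (1 - p[poly]))
  lambda <- d / sigma2
  m <- ncol(Z)
  mu <- 0
  a <- rep(0, m)
  for (it in 1:500) {
    eta <- mu + as.numeric(Z %*% a)
    pr <- stats::plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-12)
    grad <- c(sum(y - pr), as.numeric(crossprod(Z, y - pr)) - lambda * a)
    if (sqrt(sum(grad^2)) < 1e-10) break
    H <- matrix(0, m + 1, m + 1)
    H[1, 1] <- sum(w)
    H[1, -1] <- H[-1, 1] <- colSums(Z * w)
    H[-1, -1] <- crossprod(Z, Z * w) + diag(lambda, m)
    st <- solve(H, grad)
    mu <- mu + st[1]
    a <- a + st[-1]
  }
  list(mu = mu, g = as.numeric(Z %*% a))
}

# mode-only imputer: the baseline the LD imputer must beat on block-LD data
modal_imputer <- function(panel) {
  geno <- panel$genotypes
  for (j in which(colSums(is.na(geno)) > 0)) {
    tb <- table(geno[, j])
    geno[is.na(geno[, j]), j] <- as.integer(names(tb)[which.max(tb)])
  }
  genotype_panel(geno,
                 panel$markers[, c("marker_id", "chromosome", "scaffold_id", "position_bp")],
                 panel$samples[, c("sample_id", "line_id", "vigor_class")])
}

# small hand-built panel: explicit genotypes, one scaffold per chromosome
toy_panel <- function(geno, scaffold = NULL, vigor = NULL, line = NULL) {
  n <- nrow(geno)
  m <- ncol(geno)
  if (is.null(scaffold)) scaffold <- paste0("sc", seq_len(m))
  markers <- data.frame(marker_id = paste0("M", seq_len(m)),
                        chromosome = "1",
                        scaffold_id = scaffold,
                        position_bp = seq_len(m) * 100L,
                        stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0("S", seq_len(n)),
                        line_id = if (is.null(line)) paste0("L", seq_len(n)) else line,
                        vigor_class = if (is.null(vigor)) rep(NA_integer_, n) else vigor,
                        stringsAsFactors = FALSE)
  genotype_panel(geno, markers, samples)
}

# block-LD study condition: few scaffolds, many markers each, strong latent
# autocorrelation -- the regime where LD-based imputation has signal
block_ld_config <- function(seed, n_scaffolds = 20L, n_snps = 200L, ...) {
  sim_config(n_scaffolds = n_scaffolds, n_snps = n_snps,
             within_scaffold_rho = 0.95,
             missing_rate = 0, n_duplicate_samples = 0L, seed = seed, ...)
}

# study-like complete panel without the duplicate, for experiments that need
# completeness
complete_studylike <- function(seed) {
  simulate_dataset(sim_config(missing_rate = 0, n_duplicate_samples = 0L,
                              seed = seed))$panel
}
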