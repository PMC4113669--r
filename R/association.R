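#' Single-SNP logistic association scan
#'
#' For each marker fits the logistic regression
#' \eqn{\mathrm{logit}(p_i) = \mu + \beta \cdot \mathrm{dosage}_i} by Newton
#' iteration (maximum 50 iterations). Quasi-separation is flagged when
#' \eqn{|\beta|} exceeds the cap (10 log-odds units per dosage step); the
#' effect is then reported at the cap with no standard error. Monomorphic
#' markers get an undefined effect and are excluded from downstream summaries.
#'
#' @param panel a [genotype_panel()] with complete (imputed) genotypes
#' @param y binary 0/1 phenotype aligned with the panel samples (default: the
#'   panel's `vigor_class`)
#' @param beta_cap absolute log-odds bound marking quasi-separation (default 10)
#' @return data.frame with `marker_id`, `beta`, `se`, `converged`,
#'   `separation_flag`, `monomorphic`
#' @export
single_snp_scan <- function(panel, y = NULL, beta_cap = 10) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(y)) y <- panel$samples$vigor_class
  if (anyNA(panel$genotypes)) {
    stop("genotypes contain missing values; impute first (impute_missing)")
  }
  if (anyNA(y) || length(unique(y)) < 2L) {
    stop("need a complete binary phenotype with both classes present")
  }
  m <- ncol(panel$genotypes)
  out <- data.frame(marker_id = panel$markers$marker_id,
                    beta = NA_real_, se = NA_real_,
                    converged = FALSE, separation_flag = FALSE,
                    monomorphic = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    x <- panel$genotypes[, j]
    if (length(unique(x)) < 2L) {
      out$monomorphic[j] <- TRUE
      next
    }
    fit <- logistic_newton(cbind(1, x), y, max_iter = 50L, cap = beta_cap)
    out$beta[j] <- fit$beta[2L]
    out$se[j] <- fit$se[2L]
    out$converged[j] <- fit$converged
    out$separation_flag[j] <- fit$separated
  }
  out
}

# Newton (IRLS) maximum-likelihood logistic regression with a cap on the
# slope coefficient to detect quasi-separation.
logistic_newton <- function(X, y, max_iter = 50L, cap = 10, tol = 1e-10) {
  beta <- numeric(ncol(X))
  converged <- FALSE
  separated <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    grad <- as.numeric(crossprod(X, y - p))
    H <- crossprod(X, X * w)
    step <- tryCatch(solve(H, grad), error = function(e) rep(NA_real_, length(beta)))
    if (anyNA(step)) break
    beta <- beta + step
    if (any(abs(beta[-1L]) > cap)) {
      separated <- TRUE
      beta[-1L] <- sign(beta[-1L]) * pmin(abs(beta[-1L]), cap)
      break
    }
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
  }
  se <- rep(NA_real_, length(beta))
  if (converged && !separated) {
    eta <- as.numeric(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    cov <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
    if (!is.null(cov)) se <- sqrt(diag(cov))
  }
  list(beta = beta, se = se, converged = converged || separated,
       separated = separated)
}

#' Pairwise LD between two markers as genotypic r-squared
#'
#' Squared Pearson correlation of the two dosage vectors (the standard
#' unphased composite estimator); invariant to swapping which allele is
#' counted at either marker.
#'
#' @param panel a [genotype_panel()] with complete genotypes
#' @param i,j marker ids or column indices
#' @return r² in [0, 1]
#' @export
ld_r2 <- function(panel, i, j) {
  stopifnot(inherits(panel, "genotype_panel"))
  gi <- marker_column(panel, i)
  gj <- marker_column(panel, j)
  if (stats::var(gi) == 0 || stats::var(gj) == 0) {
    stop("zero-variance (monomorphic) marker: r2 undefined")
  }
  stats::cor(gi, gj)^2
}

marker_column <- function(panel, i) {
  if (is.character(i)) i <- match(i, panel$markers$marker_id)
  if (is.na(i)) stop("unknown marker id")
  panel$genotypes[, i]
}

#' Full pairwise LD (r-squared) matrix
#'
#' @param panel a [genotype_panel()] with complete genotypes
#' @return object of class `ld_matrix`: `values` (m x m r² matrix, NA rows for
#'   monomorphic markers), `marker_ids`, `scaffold_ids`
#' @export
ld_matrix <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (anyNA(panel$genotypes)) stop("genotypes contain missing values; impute first")
  v <- apply(panel$genotypes, 2L, stats::var)
  R <- matrix(NA_real_, ncol(panel$genotypes), ncol(panel$genotypes),
              dimnames = list(panel$markers$marker_id, panel$markers$marker_id))
  poly <- v > 0
  if (any(poly)) {
    R[poly, poly] <- stats::cor(panel$genotypes[, poly, drop = FALSE])^2
  }
  structure(list(values = R,
                 marker_ids = panel$markers$marker_id,
                 scaffold_ids = panel$markers$scaffold_id),
            class = "ld_matrix")
}

#' LD summaries: total, within-scaffold, and large-effect means
#'
#' Mean r² over (a) all distinct polymorphic marker pairs, (b) pairs sharing a
#' scaffold, and (c) pairs within a designated large-effect marker set, with
#' pair counts. A summary with no eligible pairs is reported as `NA`.
#'
#' @param ld an [ld_matrix()] result
#' @param large_effect_ids marker ids treated as "large effect" (e.g. from
#'   [top_effect_markers()]); optional
#' @return list with `mean_total`, `mean_within_scaffold`, `mean_large_effect`
#'   and the corresponding pair counts
#' @export
ld_summaries <- function(ld, large_effect_ids = NULL) {
  stopifnot(inherits(ld, "ld_matrix"))
  R <- ld$values
  ut <- upper.tri(R)
  ok <- ut & !is.na(R)
  mean_total <- if (any(ok)) mean(R[ok]) else NA_real_
  n_total <- sum(ok)

  same_scaffold <- outer(ld$scaffold_ids, ld$scaffold_ids, `==`)
  same_scaffold[is.na(same_scaffold)] <- FALSE
  ws <- ok & same_scaffold
  mean_ws <- if (any(ws)) mean(R[ws]) else NA_real_

  mean_le <- NA_real_
  n_le <- 0L
  if (!is.null(large_effect_ids) && length(large_effect_ids) > 1L) {
    sel <- ld$marker_ids %in% large_effect_ids
    le <- ok & outer(sel, sel, `&`)
    n_le <- sum(le)
    if (n_le > 0L) mean_le <- mean(R[le])
  }
  list(mean_total = mean_total, n_pairs_total = n_total,
       mean_within_scaffold = mean_ws, n_pairs_within_scaffold = sum(ws),
       mean_large_effect = mean_le, n_pairs_large_effect = n_le)
}

#' Markers in the top quantile of absolute association effect
#'
#' "Large effect" markers are defined as the top-q quantile of |beta| from a
#' [single_snp_scan()] (default top 10\%); separated markers count with their
#' capped effect, monomorphic markers are excluded.
#'
#' @param scan a [single_snp_scan()] result
#' @param top_q quantile fraction (default 0.10)
#' @return character vector of marker ids
#' @export
top_effect_markers <- function(scan, top_q = 0.10) {
  ok <- !scan$monomorphic & !is.na(scan$beta)
  ab <- abs(scan$beta[ok])
  thr <- stats::quantile(ab, probs = 1 - top_q, names = FALSE, type = 7)
  scan$marker_id[ok][ab >= thr]
}
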