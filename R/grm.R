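#' Compute the VanRaden genomic relationship matrix
#'
#' Realized relationships from SNP dosages:
#' \deqn{G = \frac{Z Z'}{2 \sum_i p_i (1 - p_i)}}
#' where column \eqn{i} of \eqn{Z} is the dosage at marker \eqn{i} centered by
#' twice the observed allele frequency \eqn{p_i} (equivalently, the -1/0/1
#' coding centered by \eqn{2p_i - 1}). Monomorphic markers contribute zero to
#' both numerator and denominator and are excluded from the sum.
#'
#' @param panel a [genotype_panel()]
#' @param missing_policy `"mean_impute"` replaces a missing dosage by its
#'   marker mean \eqn{2p_i} before centering (a zero in Z);
#'   `"require_complete"` errors on any missing cell. In the full pipeline
#'   genotypes are imputed first, so G normally sees complete data.
#' @param allele_freqs optional per-marker frequencies of the dosage-counted
#'   allele to center with (e.g. base-population frequencies); default: the
#'   frequencies observed in the panel.
#' @return an object of class `grm`: list with `values` (n x n symmetric
#'   matrix), `sample_ids`, `allele_freqs` (the \eqn{p_i} used), `denom`
#'   (\eqn{2\sum p_i(1-p_i)}) and `n_markers`
#' @export
compute_grm <- function(panel, missing_policy = c("mean_impute", "require_complete"),
                        allele_freqs = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  missing_policy <- match.arg(missing_policy)
  geno <- panel$genotypes
  if (nrow(geno) < 2L) stop("need at least 2 samples to compute relationships")
  if (anyNA(geno) && missing_policy == "require_complete") {
    stop("panel contains missing genotypes; impute first (see impute_missing) ",
         "or use missing_policy = 'mean_impute'")
  }
  p <- if (is.null(allele_freqs)) {
    colMeans(geno, na.rm = TRUE) / 2
  } else {
    stopifnot(length(allele_freqs) == ncol(geno),
              all(allele_freqs >= 0), all(allele_freqs <= 1))
    as.numeric(allele_freqs)
  }
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) {
    stop("denominator is zero: all markers are monomorphic")
  }
  Z <- sweep(geno, 2L, 2 * p, `-`)
  Z[is.na(Z)] <- 0  # mean imputation: dosage 2p centers to 0
  Z[, !poly] <- 0   # monomorphic markers contribute nothing
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(panel$samples$sample_id, panel$samples$sample_id)
  structure(list(values = G,
                 sample_ids = panel$samples$sample_id,
                 allele_freqs = p,
                 denom = denom,
                 n_markers = sum(poly)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$values), "samples,", x$n_markers, "polymorphic markers,",
      "denom =", signif(x$denom, 6), "\n")
  cat("  mean diagonal:", round(mean(diag(x$values)), 3),
      " mean off-diagonal:", round(mean(x$values[upper.tri(x$values)]), 3), "\n")
  invisible(x)
}

#' Summaries of a genomic relationship matrix
#'
#' Off-diagonal mean, SD and coefficient of variation (plus the all-entries
#' variants, since summary conventions differ), a line x line block-mean
#' matrix (mean relationship over cross-line sample pairs; within-line blocks
#' use off-diagonal pairs only), and the closest / farthest line pairs.
#'
#' @param grm a [compute_grm()] result
#' @param samples sample table aligned with the GRM ordering (needs columns
#'   `sample_id`, `line_id`)
#' @return an object of class `grm_summary`
#' @export
grm_summary <- function(grm, samples) {
  stopifnot(inherits(grm, "grm"))
  G <- grm$values
  n <- nrow(G)
  if (n < 2L) stop("no off-diagonal entries: GRM has a single sample")
  if (!identical(as.character(samples$sample_id), as.character(grm$sample_ids))) {
    stop("sample metadata is not aligned with the GRM ordering")
  }
  off <- G[upper.tri(G)]
  m_off <- mean(off)
  sd_off <- stats::sd(off)
  cv_off <- if (abs(m_off) < .Machine$double.eps * 100) {
    warning("off-diagonal mean is zero; coefficient of variation undefined")
    NaN
  } else 100 * sd_off / m_off
  allv <- G[row(G) >= col(G)]  # lower triangle incl. diagonal

  lines <- unique(samples$line_id)
  nl <- length(lines)
  block <- matrix(NA_real_, nl, nl, dimnames = list(lines, lines))
  for (a in seq_len(nl)) {
    ia <- which(samples$line_id == lines[a])
    for (b in seq_len(nl)) {
      ib <- which(samples$line_id == lines[b])
      if (a == b) {
        if (length(ia) > 1L) {
          sub <- G[ia, ia, drop = FALSE]
          block[a, b] <- mean(sub[upper.tri(sub)])
        }
      } else {
        block[a, b] <- mean(G[ia, ib])
      }
    }
  }
  closest <- farthest <- NULL
  if (nl > 1L) {
    cross <- block
    diag(cross) <- NA_real_
    idx_max <- which(cross == max(cross, na.rm = TRUE), arr.ind = TRUE)[1, ]
    idx_min <- which(cross == min(cross, na.rm = TRUE), arr.ind = TRUE)[1, ]
    closest <- list(lines = sort(lines[idx_max]), mean = max(cross, na.rm = TRUE))
    farthest <- list(lines = sort(lines[idx_min]), mean = min(cross, na.rm = TRUE))
  }
  structure(list(
    mean_offdiag = m_off, sd_offdiag = sd_off, cv_offdiag_pct = cv_off,
    mean_all = mean(allv), sd_all = stats::sd(allv),
    mean_diag = mean(diag(G)),
    block_means = block, closest = closest, farthest = farthest,
    n_pairs = length(off)
  ), class = "grm_summary")
}

#' @export
print.grm_summary <- function(x, ...) {
  cat(sprintf("genomic relationships: mean %.3f (SD %.3f; CV %.1f%%) over %d pairs\n",
              x$mean_offdiag, x$sd_offdiag, x$cv_offdiag_pct, x$n_pairs))
  cat(sprintf("  mean diagonal %.3f; all-entries mean %.3f\n", x$mean_diag, x$mean_all))
  if (!is.null(x$closest)) {
    cat(sprintf("  closest lines: %s-%s (%.3f); farthest: %s-%s (%.3f)\n",
                x$closest$lines[1], x$closest$lines[2], x$closest$mean,
                x$farthest$lines[1], x$farthest$lines[2], x$farthest$mean))
  }
  invisible(x)
}

#' Write a GRM to TSV (square matrix with sample-id header) plus sidecar metadata
#' @param grm a [compute_grm()] result
#' @param path output TSV path; metadata goes to `<path>.meta.yaml`
#' @return invisibly, `path`
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  df <- data.frame(sample_id = grm$sample_ids, grm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(denom = grm$denom, n_markers = grm$n_markers),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a GRM written by [write_grm()]
#' @param path TSV path
#' @return a `grm` object (allele frequencies are not persisted)
#' @export
read_grm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character"))
  ids <- as.character(df$sample_id)
  G <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(G) <- list(ids, ids)
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  structure(list(values = G, sample_ids = ids, allele_freqs = NULL,
                 denom = meta$denom %||% NA_real_,
                 n_markers = meta$n_markers %||% NA_integer_),
            class = "grm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
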