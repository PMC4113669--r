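#' LD-based imputation of missing genotypes
#'
#' Fills each missing cell from the k most LD-correlated markers on the same
#' scaffold: for a target marker, candidate predictors are same-scaffold
#' markers with pairwise-complete r² of at least `min_r2`; the top k are used
#' in a linear regression of the target dosage on the predictors (fitted on
#' samples complete for that predictor set), and the prediction is rounded to
#' the nearest valid genotype with ties going to the heterozygote. Cells with
#' no informative neighbors — or no usable predictor values in that sample —
#' fall back to the marker's modal genotype.
#'
#' @param panel a [genotype_panel()]
#' @param k number of LD neighbors used per marker (default 5)
#' @param min_r2 minimum r² for a marker to count as informative (default 0.1)
#' @return a [genotype_panel()] with no missing cells; attribute
#'   `imputed_cells` holds a data.frame (sample_id, marker_id, method) flagging
#'   the provenance of every filled cell
#' @export
impute_missing <- function(panel, k = 5L, min_r2 = 0.1) {
  stopifnot(inherits(panel, "genotype_panel"))
  geno <- panel$genotypes
  all_missing <- which(colSums(!is.na(geno)) == 0L)
  if (length(all_missing)) {
    stop("marker(s) entirely missing: ",
         paste(panel$markers$marker_id[all_missing], collapse = ", "))
  }
  miss_idx <- which(is.na(geno), arr.ind = TRUE)
  if (nrow(miss_idx) == 0L) {
    attr(panel, "imputed_cells") <- data.frame(sample_id = character(),
                                               marker_id = character(),
                                               method = character(),
                                               stringsAsFactors = FALSE)
    return(panel)
  }
  scaffold <- panel$markers$scaffold_id
  modal <- apply(geno, 2L, function(g) {
    tb <- table(g)
    as.integer(names(tb)[which.max(tb)])
  })
  prov <- character(nrow(miss_idx))

  target_markers <- unique(miss_idx[, 2L])
  for (j in target_markers) {
    rows_j <- miss_idx[miss_idx[, 2L] == j, 1L]
    mates <- which(scaffold == scaffold[j] & seq_along(scaffold) != j &
                     !is.na(scaffold))
    preds <- integer(0)
    if (length(mates)) {
      r2 <- vapply(mates, function(m) {
        ok <- !is.na(geno[, j]) & !is.na(geno[, m])
        if (sum(ok) < 3L) return(NA_real_)
        xj <- geno[ok, j]; xm <- geno[ok, m]
        if (stats::var(xj) == 0 || stats::var(xm) == 0) return(NA_real_)
        stats::cor(xj, xm)^2
      }, numeric(1))
      informative <- mates[!is.na(r2) & r2 >= min_r2]
      if (length(informative)) {
        ord <- order(r2[match(informative, mates)], decreasing = TRUE)
        preds <- informative[utils::head(ord, k)]
      }
    }
    for (s in rows_j) {
      cell <- which(miss_idx[, 1L] == s & miss_idx[, 2L] == j)
      usable <- preds[!is.na(geno[s, preds])]
      filled <- FALSE
      if (length(usable)) {
        train <- which(!is.na(geno[, j]) &
                         rowSums(is.na(geno[, usable, drop = FALSE])) == 0L)
        if (length(train) > length(usable) + 1L) {
          X <- cbind(1, geno[train, usable, drop = FALSE])
          fit <- tryCatch(qr.solve(qr(X), geno[train, j]), error = function(e) NULL)
          if (!is.null(fit)) {
            pred <- sum(c(1, geno[s, usable]) * fit)
            geno[s, j] <- round_genotype(pred)
            prov[cell] <- "ld_regression"
            filled <- TRUE
          }
        }
      }
      if (!filled) {
        geno[s, j] <- modal[j]
        prov[cell] <- "mode"
      }
    }
  }
  out <- genotype_panel(geno,
                        panel$markers[, c("marker_id", "chromosome", "scaffold_id", "position_bp")],
                        panel$samples[, c("sample_id", "line_id", "vigor_class")])
  attr(out, "imputed_cells") <- data.frame(
    sample_id = panel$samples$sample_id[miss_idx[, 1L]],
    marker_id = panel$markers$marker_id[miss_idx[, 2L]],
    method = prov, stringsAsFactors = FALSE)
  out
}

# round a regression prediction to the nearest valid genotype; ties between
# a homozygote and the heterozygote resolve toward the heterozygote
round_genotype <- function(x) {
  x <- min(max(x, 0), 2)
  d <- abs(x - 0:2)
  cands <- which(d == min(d)) - 1L
  if (length(cands) > 1L && 1L %in% cands) return(1L)
  as.integer(cands[1L])
}

#' Mask a fraction of genotype cells at random
#'
#' Sets `round(fraction * n_cells)` uniformly chosen non-missing cells to
#' missing, returning the mask for scoring. If a draw would blank out an
#' entire marker or sample it is redrawn (up to 100 times).
#'
#' @param panel a complete [genotype_panel()]
#' @param fraction fraction of cells to mask, in (0, 1)
#' @param rng_seed integer seed
#' @return list with `panel` (masked) and `mask` (two-column index matrix)
#' @export
mask_genotypes <- function(panel, fraction, rng_seed) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (anyNA(panel$genotypes)) stop("panel must be complete before masking")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  geno <- panel$genotypes
  n_cells <- length(geno)
  n_mask <- round(fraction * n_cells)
  if (n_mask < 1L) n_mask <- 1L
  for (attempt in seq_len(100L)) {
    cells <- with_seed(stage_seed(rng_seed, attempt),
                       sample.int(n_cells, n_mask))
    masked <- geno
    masked[cells] <- NA_integer_
    if (all(colSums(!is.na(masked)) > 0L) && all(rowSums(!is.na(masked)) > 0L)) {
      out <- genotype_panel(masked,
                            panel$markers[, c("marker_id", "chromosome", "scaffold_id", "position_bp")],
                            panel$samples[, c("sample_id", "line_id", "vigor_class")])
      mask <- arrayInd(cells, dim(geno))
      colnames(mask) <- c("sample", "marker")
      return(list(panel = out, mask = mask))
    }
  }
  stop("could not draw a mask leaving every marker and sample partially called")
}

#' Imputation-accuracy masking experiment
#'
#' From a complete panel, for each missing-data fraction and replicate: mask
#' cells at random, impute them back, and score the proportion of masked cells
#' whose imputed genotype exactly matches the original (exact 0/1/2 match).
#' Per-fraction means trace the empirical accuracy curve.
#'
#' @param panel a complete [genotype_panel()]
#' @param fractions missing-data fractions (default 1, 2, 3, 5, 10, 20\%)
#' @param replicates random replicates per fraction (default 5)
#' @param rng_seed integer seed
#' @param imputer function(panel) -> complete panel (default [impute_missing()];
#'   replaceable for baseline comparisons)
#' @return object of class `masking_experiment`: `fractions`, `accuracies`
#'   (per-fraction means), `per_replicate` (full table), `seed`
#' @export
accuracy_experiment <- function(panel,
                                fractions = c(0.01, 0.02, 0.03, 0.05, 0.10, 0.20),
                                replicates = 5L, rng_seed = 1L,
                                imputer = impute_missing) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (anyNA(panel$genotypes)) stop("panel must be complete (no missing cells)")
  rows <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    for (rep in seq_len(replicates)) {
      seed <- stage_seed(rng_seed, fi * 1000L + rep)
      mk <- tryCatch(mask_genotypes(panel, f, seed), error = function(e) {
        stop("masking failed at fraction ", f, " replicate ", rep, ": ",
             conditionMessage(e))
      })
      imputed <- imputer(mk$panel)
      truth <- panel$genotypes[mk$mask]
      pred <- imputed$genotypes[mk$mask]
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, replicate = rep,
        n_masked = nrow(mk$mask),
        accuracy = mean(pred == truth))
    }
  }
  per_rep <- do.call(rbind, rows)
  acc <- vapply(fractions, function(f) mean(per_rep$accuracy[per_rep$fraction == f]),
                numeric(1))
  structure(list(fractions = fractions,
                 accuracies = acc,
                 replicates_per_fraction = replicates,
                 per_replicate = per_rep,
                 seed = rng_seed),
            class = "masking_experiment")
}

#' @export
print.masking_experiment <- function(x, ...) {
  cat("imputation masking experiment (", x$replicates_per_fraction,
      "replicates per fraction )\n")
  print(data.frame(pct_missing = 100 * x$fractions,
                   accuracy = round(x$accuracies, 4)), row.names = FALSE)
  invisible(x)
}

#' Interpolate the empirical imputation-accuracy curve
#'
#' Linear interpolation of per-fraction mean accuracies at an observed missing
#' rate; reading the curve at the dataset's own missing fraction gives an
#' indirect estimate of the imputation accuracy achieved on the real data.
#'
#' @param experiment an [accuracy_experiment()] result
#' @param at_fraction query missing fraction; must lie within the measured range
#' @return interpolated accuracy
#' @export
interpolate_accuracy <- function(experiment, at_fraction) {
  stopifnot(inherits(experiment, "masking_experiment"))
  f <- experiment$fractions
  if (at_fraction < min(f) || at_fraction > max(f)) {
    stop("at_fraction ", at_fraction, " outside measured range [",
         min(f), ", ", max(f), "]: extrapolation not supported")
  }
  stats::approx(f, experiment$accuracies, xout = at_fraction, method = "linear")$y
}
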