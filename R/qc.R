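#' Quality-filter a genotype panel
#'
#' Reproduces the marker-editing pipeline used for the sugar-beet root-vigor
#' panel, in a fixed order:
#' \enumerate{
#'   \item remove duplicated samples: samples whose non-missing genotypes match
#'     another sample at 100\% of jointly called markers (the first sample in
#'     input order is kept; groups larger than two are collapsed to one);
#'   \item remove markers with call rate \eqn{\le 1 - }`max_snp_missing`
#'     (so `max_snp_missing = 0.15` removes call rate \eqn{\le 0.85}),
#'     recomputed on the remaining samples;
#'   \item recompute MAF on the remaining samples and remove markers with
#'     MAF \eqn{\le} `min_maf`.
#' }
#' Both thresholds are inclusive ("\eqn{\le}" removes), matching the editing
#' rules the panel was designed around.
#'
#' @param panel a [genotype_panel()]
#' @param max_snp_missing maximum tolerated per-marker missing fraction
#'   (default 0.15, i.e. call rate must exceed 0.85)
#' @param min_maf markers with MAF at or below this are removed (default 0.025)
#' @param drop_duplicates remove 100\%-identical samples first (default TRUE)
#' @return a list with elements `panel` (the filtered [genotype_panel()]) and
#'   `report` (a `qc_report` listing every removed id with its reason, plus
#'   remaining-missingness bookkeeping with explicit numerator and denominator)
#' @export
qc_filter <- function(panel, max_snp_missing = 0.15, min_maf = 0.025,
                      drop_duplicates = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (max_snp_missing < 0 || max_snp_missing > 1) stop("max_snp_missing must be in [0,1]")
  if (min_maf < 0 || min_maf > 1) stop("min_maf must be in [0,1]")

  removed_samples <- data.frame(sample_id = character(), reason = character(),
                                detail = character(), stringsAsFactors = FALSE)
  removed_markers <- data.frame(marker_id = character(), reason = character(),
                                value = numeric(), stringsAsFactors = FALSE)
  cur <- panel

  # stage 1: duplicate samples (100% identity over jointly called markers)
  if (drop_duplicates && nrow(cur$genotypes) > 1L) {
    dup <- find_duplicate_samples(cur$genotypes)
    if (length(dup$drop)) {
      removed_samples <- data.frame(
        sample_id = cur$samples$sample_id[dup$drop],
        reason = "duplicate",
        detail = paste0("matches ", cur$samples$sample_id[dup$keep_of]),
        stringsAsFactors = FALSE
      )
      keep <- setdiff(seq_len(nrow(cur$genotypes)), dup$drop)
      cur <- subset_panel(cur, samples = keep)
    }
  }

  # stage 2: per-marker call rate, recomputed on surviving samples
  cr <- marker_call_rates(cur$genotypes)
  low_cr <- which(cr <= 1 - max_snp_missing)
  if (length(low_cr)) {
    removed_markers <- rbind(removed_markers, data.frame(
      marker_id = cur$markers$marker_id[low_cr],
      reason = "call_rate",
      value = cr[low_cr],
      stringsAsFactors = FALSE
    ))
    if (length(low_cr) == ncol(cur$genotypes)) {
      stop("empty panel: all markers removed by the call-rate filter")
    }
    cur <- subset_panel(cur, markers = setdiff(seq_len(ncol(cur$genotypes)), low_cr))
  }

  # stage 3: MAF, recomputed on surviving samples
  maf <- marker_maf(cur$genotypes)
  low_maf <- which(is.na(maf) | maf <= min_maf)
  if (length(low_maf)) {
    removed_markers <- rbind(removed_markers, data.frame(
      marker_id = cur$markers$marker_id[low_maf],
      reason = "maf",
      value = maf[low_maf],
      stringsAsFactors = FALSE
    ))
    if (length(low_maf) == ncol(cur$genotypes)) {
      stop("empty panel: all markers removed by the MAF filter")
    }
    cur <- subset_panel(cur, markers = setdiff(seq_len(ncol(cur$genotypes)), low_maf))
  }

  n_missing <- sum(is.na(cur$genotypes))
  n_cells <- length(cur$genotypes)
  report <- structure(list(
    removed_samples = removed_samples,
    removed_markers = removed_markers,
    n_samples = nrow(cur$genotypes),
    n_markers = ncol(cur$genotypes),
    n_missing = n_missing,
    n_cells = n_cells,
    missing_pct = 100 * n_missing / n_cells,
    thresholds = c(max_snp_missing = max_snp_missing, min_maf = min_maf)
  ), class = "qc_report")

  list(panel = cur, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat("  removed samples:", nrow(x$removed_samples), "\n")
  if (nrow(x$removed_samples)) {
    for (i in seq_len(nrow(x$removed_samples))) {
      cat("    ", x$removed_samples$sample_id[i], "-", x$removed_samples$reason[i],
          paste0("(", x$removed_samples$detail[i], ")"), "\n")
    }
  }
  cat("  removed markers:", nrow(x$removed_markers),
      sprintf("(call-rate: %d, MAF: %d)\n",
              sum(x$removed_markers$reason == "call_rate"),
              sum(x$removed_markers$reason == "maf")))
  cat("  surviving panel:", x$n_samples, "samples x", x$n_markers, "markers\n")
  cat(sprintf("  missing genotypes remaining: %d of %d cells (%.2f%%)\n",
              x$n_missing, x$n_cells, x$missing_pct))
  invisible(x)
}

#' Find duplicated samples (100\% identity over jointly called genotypes)
#'
#' Two samples are duplicates when every marker called in both carries the
#' same genotype and at least one marker is jointly called. For each duplicate
#' group the first sample in input order is kept.
#'
#' @param genotypes dosage matrix
#' @return list with integer vectors `drop` (row indices to remove) and
#'   `keep_of` (for each dropped row, the retained row it matched)
#' @keywords internal
find_duplicate_samples <- function(genotypes) {
  n <- nrow(genotypes)
  drop <- integer(0)
  keep_of <- integer(0)
  dropped <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) {
    if (dropped[i]) next
    gi <- genotypes[i, ]
    for (j in seq.int(i + 1L, n)) {
      if (dropped[j]) next
      gj <- genotypes[j, ]
      joint <- !is.na(gi) & !is.na(gj)
      if (any(joint) && all(gi[joint] == gj[joint])) {
        dropped[j] <- TRUE
        drop <- c(drop, j)
        keep_of <- c(keep_of, i)
      }
    }
  }
  list(drop = drop, keep_of = keep_of)
}

#' Missingness bookkeeping for a panel
#'
#' Counts missing genotype cells and expresses them as a percentage of all
#' cells, printing both numerator and denominator so alternative denominator
#' conventions can be checked directly.
#'
#' @param panel a [genotype_panel()]
#' @return list with `n_missing`, `n_cells`, `pct` (percentage, 2 d.p. on print)
#' @export
missingness_report <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  n_missing <- sum(is.na(panel$genotypes))
  n_cells <- length(panel$genotypes)
  structure(list(n_missing = n_missing, n_cells = n_cells,
                 pct = 100 * n_missing / n_cells),
            class = "missingness_report")
}

#' @export
print.missingness_report <- function(x, ...) {
  cat(sprintf("%d missing genotypes of %d cells (%.2f%%)\n",
              x$n_missing, x$n_cells, x$pct))
  invisible(x)
}
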