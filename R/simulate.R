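#' Configuration for a synthetic line-structured population
#'
#' Defaults emulate the sugar-beet root-vigor study design: 18 inbred-derived
#' lines (15 high-vigor with 100 plants, 3 low-vigor with 24), 192 SNPs spread
#' over 99 scaffolds across 9 chromosomes plus unassigned, MAF drawn between
#' 0.05 and 0.5 (mean ~0.27), strong within-scaffold LD and independence
#' between scaffolds, an oligogenic liability trait (10 QTL clustered on a few
#' scaffolds) with heritability 0.783 on the logistic-liability scale, 3\%
#' random missingness and one exactly duplicated sample.
#'
#' @param n_lines_high,n_lines_low numbers of high- and low-vigor lines
#' @param samples_per_line integer vector of per-line sample counts, ordered
#'   high-vigor lines first (default: study-like 100 + 24 allocation)
#' @param n_scaffolds number of scaffolds
#' @param n_snps total number of SNP markers
#' @param within_scaffold_rho latent AR(1) correlation between adjacent markers
#'   of a scaffold, in [0, 1)
#' @param maf_range minor-allele-frequency range for founder allele frequencies
#' @param n_founder_pool size of the shared ancestral haplotype pool the line
#'   founders are drawn from; a small pool makes the lines related to one
#'   another, as in a closed breeding program
#' @param line_divergence per-allele flip probability applied when a line
#'   copies a pool haplotype (line-specific divergence from the ancestors)
#' @param founder_het per-allele probability that a line's second founder
#'   haplotype differs from its first: residual heterozygosity of the inbred
#'   lines
#' @param n_qtl number of causal markers
#' @param qtl_effect_size relative magnitude of QTL effects (the whole genetic
#'   value is rescaled to hit `target_h2`, so only ratios matter)
#' @param target_h2 realized liability-scale heritability of the trait
#' @param qtl_line_polarization probability that a founder haplotype of a
#'   high-vigor line carries the favorable allele at a QTL (and a low-vigor
#'   line the unfavorable one). Models the divergent selection that produced
#'   the contrasting lines; 0.5 disables polarization.
#' @param mu liability intercept: controls class prevalence (default 2.2,
#'   giving roughly the study's 100:24 high:low balance)
#' @param noise_rate per-allele within-line Mendelian/genotyping noise
#' @param missing_rate missing-completely-at-random rate for the masked panel
#' @param n_duplicate_samples exactly duplicated samples appended to the panel
#' @param seed integer seed
#' @return a `sim_config` list, validated
#' @export
sim_config <- function(n_lines_high = 15L, n_lines_low = 3L,
                       samples_per_line = NULL,
                       n_scaffolds = 99L, n_snps = 192L,
                       within_scaffold_rho = 0.9,
                       maf_range = c(0.05, 0.5),
                       n_founder_pool = 4L, line_divergence = 0.02,
                       founder_het = 0.03,
                       n_qtl = 10L, qtl_effect_size = 1,
                       target_h2 = 0.783, qtl_line_polarization = 1,
                       mu = 2.2,
                       noise_rate = 0.02,
                       missing_rate = 0.03, n_duplicate_samples = 1L,
                       seed = 1L) {
  n_lines <- n_lines_high + n_lines_low
  if (is.null(samples_per_line)) {
    samples_per_line <- default_line_sizes(n_lines_high, n_lines_low)
  }
  if (length(samples_per_line) == 1L) {
    samples_per_line <- rep(samples_per_line, n_lines)
  }
  cfg <- list(n_lines_high = as.integer(n_lines_high),
              n_lines_low = as.integer(n_lines_low),
              samples_per_line = as.integer(samples_per_line),
              n_scaffolds = as.integer(n_scaffolds),
              n_snps = as.integer(n_snps),
              within_scaffold_rho = within_scaffold_rho,
              maf_range = maf_range,
              n_founder_pool = as.integer(n_founder_pool),
              line_divergence = line_divergence,
              founder_het = founder_het,
              n_qtl = as.integer(n_qtl),
              qtl_effect_size = qtl_effect_size,
              target_h2 = target_h2,
              qtl_line_polarization = qtl_line_polarization,
              mu = mu,
              noise_rate = noise_rate,
              missing_rate = missing_rate,
              n_duplicate_samples = as.integer(n_duplicate_samples),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

default_line_sizes <- function(n_high, n_low) {
  # mirror the study's allocation when the line counts match it: 99 unique
  # high-vigor plants (100 including the duplicated one) and 24 low-vigor,
  # otherwise spread evenly
  if (n_high == 15L && n_low == 3L) {
    c(rep(7L, 9L), rep(6L, 6L), rep(8L, 3L))
  } else {
    rep(7L, n_high + n_low)
  }
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_lines_high >= 1L, cfg$n_lines_low >= 0L,
            all(cfg$samples_per_line >= 1L),
            length(cfg$samples_per_line) == cfg$n_lines_high + cfg$n_lines_low,
            cfg$n_scaffolds >= 1L, cfg$n_snps >= cfg$n_scaffolds,
            cfg$within_scaffold_rho >= 0, cfg$within_scaffold_rho < 1,
            cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
            cfg$maf_range[1] <= cfg$maf_range[2],
            cfg$n_founder_pool >= 1L,
            cfg$line_divergence >= 0, cfg$line_divergence < 0.5,
            cfg$founder_het >= 0, cfg$founder_het < 0.5,
            cfg$n_qtl >= 0L,
            cfg$target_h2 >= 0, cfg$target_h2 < 1,
            cfg$qtl_line_polarization >= 0, cfg$qtl_line_polarization <= 1,
            cfg$noise_rate >= 0, cfg$noise_rate < 0.5,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$n_duplicate_samples >= 0L)
  if (cfg$target_h2 > 0 && cfg$n_qtl == 0L) {
    stop("unattainable configuration: target_h2 > 0 requires n_qtl >= 1")
  }
  invisible(cfg)
}

#' Simulate a line-structured population with a binary liability trait
#'
#' Generative model (mirroring the analysis model run forward):
#' \enumerate{
#'   \item markers are laid out on scaffolds assigned to chromosomes 1-9 or
#'     unassigned; for every line and scaffold, two founder haplotypes are
#'     drawn from a Gaussian copula with AR(1) latent correlation
#'     `within_scaffold_rho` between adjacent markers (independent across
#'     scaffolds), thresholded at the marker's allele frequency;
#'   \item each sample inherits, per scaffold, one of the line's two founder
#'     haplotypes for each of its own two haplotypes, plus rare per-allele
#'     flips (`noise_rate`), giving high within-line relationships;
#'   \item `n_qtl` causal markers are chosen clustered on a few scaffolds;
#'     the genetic value \eqn{g_i} is the effect-weighted sum of centered
#'     dosages, rescaled so that
#'     \eqn{\mathrm{Var}(g)/(\mathrm{Var}(g)+\pi^2/3)} equals `target_h2`
#'     exactly in the realized sample;
#'   \item liability \eqn{l_i = \mu + g_i + e_i} with standard-logistic
#'     \eqn{e_i}; class \eqn{y_i = 1} iff \eqn{l_i > 0}; line labels
#'     HIGH1..HIGHn / LOW1..LOWn are assigned by line-mean liability so the
#'     configured numbers of high and low lines are met;
#'   \item optionally, samples are duplicated exactly and missingness is
#'     injected completely at random into a copy of the panel.
#' }
#'
#' @param config a [sim_config()]
#' @return object of class `sim_dataset`: `panel` (complete
#'   [genotype_panel()], duplicates included), `masked_panel` (with MCAR
#'   missingness, NULL when `missing_rate = 0`), and `truth` (true genetic
#'   values, QTL ids and effects, realized h², liabilities, the config)
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n_lines <- cfg$n_lines_high + cfg$n_lines_low
  m <- cfg$n_snps

  # marker map: scaffolds sized to total n_snps, assigned to chromosomes
  sizes <- rep(m %/% cfg$n_scaffolds, cfg$n_scaffolds)
  extra <- m - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes <- sample(sizes)  # shuffle which scaffolds are big
  scaffold_ids <- sprintf("scaffold%05d", seq_len(cfg$n_scaffolds))
  chrom_pool <- c(as.character(1:9), "unassigned")
  scaffold_chrom <- sample(chrom_pool, cfg$n_scaffolds, replace = TRUE)
  scaffold_of <- rep(seq_len(cfg$n_scaffolds), times = sizes)
  markers <- data.frame(
    marker_id = sprintf("SNP%03d", seq_len(m)),
    chromosome = scaffold_chrom[scaffold_of],
    scaffold_id = scaffold_ids[scaffold_of],
    position_bp = unlist(lapply(sizes, function(s) sort(sample.int(2e6, s)))),
    stringsAsFactors = FALSE
  )

  # founder allele frequencies: MAF in range, dosage-counted allele random
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  p <- ifelse(stats::runif(m) < 0.5, maf, 1 - maf)

  # founder haplotypes per line: Gaussian-copula AR(1) within scaffold
  draw_haplotype <- function() {
    hap <- integer(m)
    for (sc in seq_len(cfg$n_scaffolds)) {
      idx <- which(scaffold_of == sc)
      z <- numeric(length(idx))
      z[1] <- stats::rnorm(1)
      if (length(idx) > 1L) {
        for (t in 2:length(idx)) {
          z[t] <- cfg$within_scaffold_rho * z[t - 1] +
            sqrt(1 - cfg$within_scaffold_rho^2) * stats::rnorm(1)
        }
      }
      hap[idx] <- as.integer(z < stats::qnorm(p[idx]))
    }
    hap
  }
  # QTL: clustered on a few scaffolds (the biggest, so neighbors exist to tag
  # the causal alleles)
  qtl <- integer(0)
  effects <- numeric(0)
  qtl_scaffolds <- integer(0)
  if (cfg$n_qtl > 0L) {
    n_qtl_scaffolds <- max(1L, ceiling(cfg$n_qtl / 4))
    big <- order(sizes, decreasing = TRUE)
    qtl_scaffolds <- big[seq_len(min(n_qtl_scaffolds, cfg$n_scaffolds))]
    cand <- which(scaffold_of %in% qtl_scaffolds)
    while (length(cand) < cfg$n_qtl) {
      n_qtl_scaffolds <- n_qtl_scaffolds + 1L
      qtl_scaffolds <- big[seq_len(min(n_qtl_scaffolds, cfg$n_scaffolds))]
      cand <- which(scaffold_of %in% qtl_scaffolds)
    }
    qtl <- sort(sample(cand, cfg$n_qtl))
    effects <- cfg$qtl_effect_size * stats::runif(cfg$n_qtl, 0.5, 1.5) *
      sample(c(-1, 1), cfg$n_qtl, replace = TRUE)
  }

  # shared ancestry: all lines draw founder haplotypes as per-scaffold mosaics
  # of a small ancestral pool, so between-line relatedness is substantial, as
  # in a closed breeding program. Divergent selection is modelled through two
  # class archetype haplotypes per QTL scaffold (favorable / unfavorable
  # alleles at the scaffold's QTL, otherwise a fresh copula draw): a line of a
  # given type copies its own class's archetype there with probability
  # qtl_line_polarization, which also creates the within-scaffold LD between
  # QTL and their neighboring markers.
  pool <- lapply(seq_len(cfg$n_founder_pool), function(i) draw_haplotype())
  archetype <- NULL
  if (length(qtl) && cfg$n_lines_low > 0L) {
    archetype <- list(high = draw_haplotype(), low = draw_haplotype())
    fav <- as.integer(effects > 0)
    archetype$high[qtl] <- fav
    archetype$low[qtl] <- 1L - fav
  }
  low_type <- if (cfg$n_lines_low > 0L) sample.int(n_lines, cfg$n_lines_low) else integer(0)
  mutate_hap <- function(hap, rate) {
    if (rate > 0) {
      flip <- stats::runif(m) < rate
      hap[flip] <- 1L - hap[flip]
    }
    hap
  }
  draw_founder_high <- function() {
    pick <- sample.int(cfg$n_founder_pool, cfg$n_scaffolds, replace = TRUE)
    hap <- integer(m)
    for (sc in seq_len(cfg$n_scaffolds)) {
      idx <- which(scaffold_of == sc)
      if (!is.null(archetype) && sc %in% qtl_scaffolds) {
        src <- if (stats::runif(1) < cfg$qtl_line_polarization) archetype$high else archetype$low
        hap[idx] <- src[idx]
      } else {
        hap[idx] <- pool[[pick[sc]]][idx]
      }
    }
    mutate_hap(hap, cfg$line_divergence)
  }
  # The lines are inbred (second founder haplotype = lightly mutated copy of
  # the first, residual heterozygosity founder_het), so plants within a line
  # are near-identical and the phenotype is nearly line-consistent. Each
  # low-vigor line is derived from a "sister" high-vigor line by divergent
  # selection: it shares the sister's genome except on the QTL scaffolds,
  # where it (usually) carries the unfavorable archetype. This reproduces the
  # study population, where the low lines shared most of their genetic basis
  # with closely related high lines and differed at the vigor loci.
  founders <- vector("list", n_lines)
  high_idx <- setdiff(seq_len(n_lines), low_type)
  for (l in high_idx) {
    h1 <- draw_founder_high()
    founders[[l]] <- list(h1, mutate_hap(h1, cfg$founder_het))
  }
  if (length(low_type)) {
    sisters <- sample(high_idx, length(low_type),
                      replace = length(high_idx) < length(low_type))
    for (i in seq_along(low_type)) {
      h1 <- founders[[sisters[i]]][[1]]
      if (!is.null(archetype)) {
        for (sc in qtl_scaffolds) {
          if (stats::runif(1) < cfg$qtl_line_polarization) {
            idx <- which(scaffold_of == sc)
            h1[idx] <- archetype$low[idx]
          }
        }
      }
      h1 <- mutate_hap(h1, cfg$line_divergence)
      founders[[low_type[i]]] <- list(h1, mutate_hap(h1, cfg$founder_het))
    }
  }

  # provisional line ranking by founder genetic mean -> sample counts:
  # the lowest-ranked lines receive the low-vigor allocations
  founder_g <- vapply(founders, function(f) {
    if (!length(qtl)) return(0)
    dose <- f[[1]][qtl] + f[[2]][qtl]
    sum(effects * (dose - 2 * p[qtl]))
  }, numeric(1))
  rank_order <- order(founder_g)  # ascending: lowest first
  counts <- integer(n_lines)
  high_counts <- cfg$samples_per_line[seq_len(cfg$n_lines_high)]
  low_counts <- cfg$samples_per_line[cfg$n_lines_high + seq_len(cfg$n_lines_low)]
  counts[rank_order[seq_len(cfg$n_lines_low)]] <- low_counts
  counts[rank_order[-seq_len(cfg$n_lines_low)]] <- high_counts

  # samples: per scaffold, pick one of the two founder haplotypes for each of
  # the sample's haplotypes; rare allele flips model within-line variation
  n <- sum(counts)
  geno <- matrix(0L, n, m)
  line_of <- integer(n)
  row <- 0L
  for (l in seq_len(n_lines)) {
    for (s in seq_len(counts[l])) {
      row <- row + 1L
      line_of[row] <- l
      hsum <- integer(m)
      for (h in 1:2) {
        pick <- sample(1:2, cfg$n_scaffolds, replace = TRUE)
        hap <- integer(m)
        for (sc in seq_len(cfg$n_scaffolds)) {
          idx <- which(scaffold_of == sc)
          hap[idx] <- founders[[l]][[pick[sc]]][idx]
        }
        if (cfg$noise_rate > 0) {
          flip <- stats::runif(m) < cfg$noise_rate
          hap[flip] <- 1L - hap[flip]
        }
        hsum <- hsum + hap
      }
      geno[row, ] <- hsum
    }
  }

  # genetic values rescaled to hit the target heritability exactly
  g <- numeric(n)
  if (length(qtl)) {
    p_real <- colMeans(geno[, qtl, drop = FALSE]) / 2
    Zq <- sweep(geno[, qtl, drop = FALSE], 2L, 2 * p_real, `-`)
    g_raw <- as.numeric(Zq %*% effects)
    v_raw <- stats::var(g_raw)
    if (cfg$target_h2 > 0) {
      if (v_raw < .Machine$double.eps) {
        stop("unattainable configuration: QTL carry no variance in the realized sample")
      }
      scale <- sqrt(variance_from_h2(cfg$target_h2) / v_raw)
    } else {
      scale <- 0
    }
    g <- g_raw * scale
    effects <- effects * scale
  }
  e <- stats::rlogis(n)
  liability <- cfg$mu + g + e
  y <- as.integer(liability > 0)

  # line labels by realized line-mean liability
  line_mean_l <- tapply(liability, line_of, mean)
  ord <- order(line_mean_l)  # ascending
  label <- character(n_lines)
  label[ord[seq_len(cfg$n_lines_low)]] <- paste0("LOW", seq_len(cfg$n_lines_low))
  label[ord[-seq_len(cfg$n_lines_low)]] <- paste0("HIGH", seq_len(cfg$n_lines_high))

  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    line_id = label[line_of],
    vigor_class = y,
    stringsAsFactors = FALSE
  )

  truth_g <- g
  # exact duplicates appended at the end, drawn from high-vigor lines when
  # possible (as in the study, where the duplicated plant was high-vigor)
  if (cfg$n_duplicate_samples > 0L) {
    high_rows <- which(startsWith(samples$line_id, "HIGH"))
    src_pool <- if (length(high_rows) >= cfg$n_duplicate_samples) high_rows else seq_len(n)
    dup_src <- sample(src_pool, cfg$n_duplicate_samples)
    geno <- rbind(geno, geno[dup_src, , drop = FALSE])
    dup_samples <- samples[dup_src, , drop = FALSE]
    dup_samples$sample_id <- paste0(dup_samples$sample_id, "dup")
    samples <- rbind(samples, dup_samples)
    truth_g <- c(truth_g, g[dup_src])
  }

  panel <- genotype_panel(geno, markers, samples)
  masked <- NULL
  if (cfg$missing_rate > 0) {
    masked <- inject_missing(panel, cfg$missing_rate,
                             stage_seed(cfg$seed, 7919L))
  }
  structure(list(
    panel = panel,
    masked_panel = masked,
    truth = list(g = stats::setNames(truth_g, samples$sample_id),
                 qtl_ids = markers$marker_id[qtl],
                 qtl_effects = stats::setNames(effects, markers$marker_id[qtl]),
                 realized_h2 = if (length(qtl)) {
                   stats::var(g) / (stats::var(g) + logistic_variance())
                 } else 0,
                 liability = liability,
                 config = cfg)
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("simulated dataset:", nrow(x$panel$genotypes), "samples x",
      ncol(x$panel$genotypes), "markers;",
      length(x$truth$qtl_ids), "QTL; realized h2 =",
      round(x$truth$realized_h2, 3), "\n")
  invisible(x)
}

#' Inject missing-completely-at-random genotypes
#'
#' Sets `round(rate * n_cells)` uniformly chosen cells to missing;
#' deterministic under the seed. `rate = 0` returns the panel unchanged.
#'
#' @param panel a [genotype_panel()]
#' @param rate missing rate in [0, 1)
#' @param seed integer seed
#' @return a [genotype_panel()] with injected missingness
#' @export
inject_missing <- function(panel, rate, seed) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(panel)
  geno <- panel$genotypes
  n_mask <- round(rate * length(geno))
  cells <- with_seed(seed, sample.int(length(geno), n_mask))
  geno[cells] <- NA_integer_
  genotype_panel(geno,
                 panel$markers[, c("marker_id", "chromosome", "scaffold_id", "position_bp")],
                 panel$samples[, c("sample_id", "line_id", "vigor_class")])
}

#' Write a simulated dataset: panel TSVs plus a truth file
#'
#' Writes the three TSVs of the genotype-table dialect (from the masked panel
#' when present, since that is what a real study would observe) plus
#' `truth.tsv` (per-sample true genetic value) and `truth_qtl.tsv` (QTL ids
#' and effects) and `truth.yaml` (realized h², config).
#'
#' @param sim a [simulate_dataset()] result
#' @param dir output directory
#' @return invisibly, `dir`
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_panel(sim$masked_panel %||% sim$panel, dir)
  utils::write.table(
    data.frame(sample_id = names(sim$truth$g), g_true = as.numeric(sim$truth$g)),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(marker_id = sim$truth$qtl_ids,
               effect = as.numeric(sim$truth$qtl_effects)),
    file.path(dir, "truth_qtl.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(realized_h2 = sim$truth$realized_h2,
                        config = unclass(sim$truth$config)),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Construct the QC acceptance fixture
#'
#' Builds a 124-sample x 192-marker panel carrying exactly the defects the
#' editing pipeline is specified to remove: one exactly duplicated sample, one
#' marker at call rate ~0.80, and sixteen markers at MAF ~0.012, with every
#' other marker guaranteed polymorphic above the MAF threshold and fully
#' called. Filtering at the standard thresholds (call rate <= 0.85 and MAF
#' <= 0.025 removed) must leave 123 samples and 175 markers.
#'
#' @param seed integer seed
#' @return list with `panel` and `expected` (list: n_samples = 123,
#'   n_markers = 175)
#' @export
make_qc_fixture <- function(seed = 1L) {
  cfg <- sim_config(
    samples_per_line = c(rep(7L, 9L), rep(6L, 6L), rep(8L, 3L)),  # 99 + 24
    missing_rate = 0, n_duplicate_samples = 0L, seed = seed
  )
  sim <- simulate_dataset(cfg)
  geno <- sim$panel$genotypes
  n <- nrow(geno)  # 123 unique samples
  stopifnot(n == 123L, ncol(geno) == 192L)

  with_seed(stage_seed(seed, 101L), {
    defect_markers <- sample.int(ncol(geno), 17L)
    lowcr_marker <- defect_markers[1L]
    lowmaf_markers <- defect_markers[-1L]

    # call-rate defect: 25 of 124 cells missing -> call rate 0.798
    masked_samples <- sample.int(n, 25L)
    geno[masked_samples, lowcr_marker] <- NA_integer_

    # MAF defects: 3 heterozygotes among 123 samples -> MAF 3/246 = 0.012
    for (j in lowmaf_markers) {
      col <- rep(0L, n)
      col[sample.int(n, 3L)] <- 1L
      geno[, j] <- col
    }

    # guarantee every other marker clears the MAF filter (line-structured
    # sampling can push realized MAF low): raise minor-allele counts to > 3%
    other <- setdiff(seq_len(ncol(geno)), defect_markers)
    target <- ceiling(0.031 * 2 * n)
    for (j in other) {
      dose <- geno[, j]
      cnt1 <- sum(dose)
      minor_is_one <- cnt1 <= n  # count of "1" alleles vs "0" alleles
      minor_count <- if (minor_is_one) cnt1 else 2L * n - cnt1
      deficit <- target - minor_count
      if (deficit > 0L) {
        if (minor_is_one) {
          cand <- which(dose == 0L)
          flip <- cand[seq_len(min(deficit, length(cand)))]
          geno[flip, j] <- 1L
        } else {
          cand <- which(dose == 2L)
          flip <- cand[seq_len(min(deficit, length(cand)))]
          geno[flip, j] <- 1L
        }
      }
    }

    # exact duplicate of the first sample (kept-first rule drops the copy)
    dup_of <- 1L
    geno <- rbind(geno, geno[dup_of, , drop = FALSE])
    samples <- sim$panel$samples[, c("sample_id", "line_id", "vigor_class")]
    dup_row <- samples[dup_of, , drop = FALSE]
    dup_row$sample_id <- paste0(dup_row$sample_id, "dup")
    samples <- rbind(samples, dup_row)
  })

  panel <- genotype_panel(
    geno,
    sim$panel$markers[, c("marker_id", "chromosome", "scaffold_id", "position_bp")],
    samples
  )
  list(panel = panel, expected = list(n_samples = 123L, n_markers = 175L))
}
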