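#' Construct a genotype panel
#'
#' A genotype panel bundles a samples x markers dosage matrix (0/1/2 counts of
#' a designated reference allele, `NA` for missing) with per-marker metadata
#' (chromosome, scaffold, position) and per-sample metadata (line id, binary
#' vigor class). It is the object every pipeline stage consumes.
#'
#' @param genotypes integer matrix, samples in rows, markers in columns;
#'   entries in \{0, 1, 2, NA\}. Row and column names, if present, must agree
#'   with the metadata ids.
#' @param markers data.frame with columns `marker_id`, `chromosome` (1-9 or
#'   `"unassigned"`), `scaffold_id`, `position_bp` (non-negative integer or NA)
#' @param samples data.frame with columns `sample_id`, `line_id`,
#'   `vigor_class` (0 = low, 1 = high, NA = unknown)
#' @return an object of class `genotype_panel` with per-sample and per-marker
#'   call rates and per-marker MAF precomputed
#' @export
genotype_panel <- function(genotypes, markers, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  required_m <- c("marker_id", "chromosome", "scaffold_id", "position_bp")
  missing_m <- setdiff(required_m, names(markers))
  if (length(missing_m)) {
    stop("marker table lacks column(s): ", paste(missing_m, collapse = ", "))
  }
  required_s <- c("sample_id", "line_id", "vigor_class")
  missing_s <- setdiff(required_s, names(samples))
  if (length(missing_s)) {
    stop("sample table lacks column(s): ", paste(missing_s, collapse = ", "))
  }

  if (nrow(genotypes) != nrow(samples)) {
    stop("genotype matrix has ", nrow(genotypes), " rows but sample table has ",
         nrow(samples), " entries")
  }
  if (ncol(genotypes) != nrow(markers)) {
    stop("genotype matrix has ", ncol(genotypes), " columns but marker table has ",
         nrow(markers), " entries")
  }
  if (anyDuplicated(markers$marker_id)) {
    stop("duplicate marker_id in marker table: ",
         paste(unique(markers$marker_id[duplicated(markers$marker_id)]), collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in sample table: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype entries must be 0, 1, 2 or NA")
  }
  rownames(genotypes) <- samples$sample_id
  colnames(genotypes) <- markers$marker_id

  markers$call_rate <- marker_call_rates(genotypes)
  markers$maf <- marker_maf(genotypes)
  samples$call_rate <- sample_call_rates(genotypes)

  structure(
    list(genotypes = genotypes, markers = markers, samples = samples),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  n_miss <- sum(is.na(x$genotypes))
  cat("genotype_panel:", nrow(x$genotypes), "samples x", ncol(x$genotypes),
      "markers\n")
  cat("  lines:", length(unique(x$samples$line_id)),
      " | missing cells:", n_miss,
      sprintf("(%.2f%%)\n", 100 * n_miss / length(x$genotypes)))
  cat("  mean MAF:", round(mean(x$markers$maf, na.rm = TRUE), 3),
      " | mean marker call rate:", round(mean(x$markers$call_rate), 3), "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

#' Per-marker call rates
#' @param genotypes dosage matrix with NA for missing
#' @return numeric vector, fraction of non-missing entries per column
#' @keywords internal
marker_call_rates <- function(genotypes) {
  colMeans(!is.na(genotypes))
}

#' Per-sample call rates
#' @keywords internal
sample_call_rates <- function(genotypes) {
  rowMeans(!is.na(genotypes))
}

#' Per-marker minor allele frequency
#'
#' Frequency of the less frequent allele computed from dosage counts over
#' non-missing genotypes; always in [0, 0.5]. Markers with no calls get NA.
#'
#' @param genotypes dosage matrix
#' @return numeric vector of MAF per marker
#' @export
marker_maf <- function(genotypes) {
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- NA_real_
  maf
}

#' Reference-allele frequency per marker (dosage-counted allele)
#' @keywords internal
allele_freqs <- function(genotypes) {
  colMeans(genotypes, na.rm = TRUE) / 2
}

#' Load a genotype panel from disk
#'
#' Reads either the package's tab-separated dialect (genotype table plus
#' optional marker map and sample table) or a VCF of biallelic SNPs.
#'
#' Table dialect: the genotype table is a TSV whose first column is
#' `sample_id`, remaining columns are markers, cells in \{0,1,2,NA\}. The
#' marker map is a TSV with columns `marker_id`, `chromosome` (`0` means
#' unassigned), `scaffold_id`, `position_bp`; the sample table has columns
#' `sample_id`, `line_id`, `vigor_class` in \{0,1,NA\}. For VCF input the GT
#' field is read (dosage = ALT allele count, `./.` = missing) and the marker
#' map is built from CHROM/POS/ID with scaffold = CHROM.
#'
#' @param path path to the genotype table or VCF file
#' @param format `"table"` or `"vcf"`
#' @param map_path optional marker-map TSV (table format; ignored for VCF)
#' @param sample_path optional sample-table TSV
#' @return a [genotype_panel()]
#' @export
load_genotypes <- function(path, format = c("table", "vcf"),
                           map_path = NULL, sample_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "table") {
    load_genotypes_table(path, map_path, sample_path)
  } else {
    load_genotypes_vcf(path, sample_path)
  }
}

load_genotypes_table <- function(path, map_path, sample_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = "NA")
  if (ncol(tab) < 2L) stop("malformed genotype table (need sample_id + markers): ", path)
  sample_ids <- as.character(tab[[1L]])
  geno <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(geno) <- "integer")
  bad_cells <- which(!is.na(geno) & !(geno %in% 0:2), arr.ind = TRUE)
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  non_numeric <- which(is.na(geno) & !is.na(raw) & raw != "NA", arr.ind = TRUE)
  bad <- rbind(bad_cells, non_numeric)
  if (nrow(bad)) {
    stop("malformed genotype at line ", bad[1, 1] + 1L, ", marker '",
         colnames(geno)[bad[1, 2]], "' in ", path)
  }
  marker_ids <- colnames(geno)

  if (!is.null(map_path)) {
    map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
    map$marker_id <- as.character(map$marker_id)
    missing_map <- setdiff(marker_ids, map$marker_id)
    if (length(missing_map)) {
      stop("marker map lacks entries for: ", paste(utils::head(missing_map, 5), collapse = ", "))
    }
    map <- map[match(marker_ids, map$marker_id), , drop = FALSE]
    map$chromosome <- ifelse(as.character(map$chromosome) %in% as.character(1:9),
                             as.character(map$chromosome), "unassigned")
  } else {
    map <- data.frame(marker_id = marker_ids, chromosome = "unassigned",
                      scaffold_id = NA_character_, position_bp = NA_integer_,
                      stringsAsFactors = FALSE)
  }

  if (!is.null(sample_path)) {
    st <- utils::read.delim(sample_path, stringsAsFactors = FALSE,
                            colClasses = c(sample_id = "character"))
    st$sample_id <- as.character(st$sample_id)
    missing_s <- setdiff(sample_ids, st$sample_id)
    if (length(missing_s)) {
      stop("sample table lacks entries for: ", paste(utils::head(missing_s, 5), collapse = ", "))
    }
    st <- st[match(sample_ids, st$sample_id), , drop = FALSE]
  } else {
    st <- data.frame(sample_id = sample_ids, line_id = NA_character_,
                     vigor_class = NA_integer_, stringsAsFactors = FALSE)
  }
  genotype_panel(geno, map, st)
}

load_genotypes_vcf <- function(path, sample_path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix  # matrix with CHROM POS ID REF ALT QUAL FILTER INFO
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1L |
    (!is.na(fix[, "ALT"]) & nchar(fix[, "ALT"]) != 1L)
  if (any(multi)) {
    stop("non-biallelic-SNP VCF record at line for ", fix[which(multi)[1], "CHROM"],
         ":", fix[which(multi)[1], "POS"])
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dose <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c("./.", ".|.", ".")) return(NA_integer_)
    alleles <- strsplit(x, "[/|]")[[1]]
    if (!all(alleles %in% c("0", "1"))) {
      stop("unsupported GT value '", x, "' (only biallelic 0/1 genotypes)")
    }
    sum(alleles == "1")
  })
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  map <- data.frame(
    marker_id = ids,
    chromosome = ifelse(fix[, "CHROM"] %in% as.character(1:9), fix[, "CHROM"], "unassigned"),
    scaffold_id = fix[, "CHROM"],
    position_bp = as.integer(fix[, "POS"]),
    stringsAsFactors = FALSE
  )
  geno <- t(dose)  # samples x markers
  sample_ids <- rownames(geno)
  if (!is.null(sample_path)) {
    st <- utils::read.delim(sample_path, stringsAsFactors = FALSE)
    st$sample_id <- as.character(st$sample_id)
    st <- st[match(sample_ids, st$sample_id), , drop = FALSE]
    st$sample_id <- sample_ids
  } else {
    st <- data.frame(sample_id = sample_ids, line_id = NA_character_,
                     vigor_class = NA_integer_, stringsAsFactors = FALSE)
  }
  genotype_panel(geno, map, st)
}

#' Write a genotype panel to a directory in the package's TSV dialect
#'
#' Writes `genotypes.tsv`, `markers.tsv` and `samples.tsv`; the inverse of
#' [load_genotypes()] with `format = "table"`.
#'
#' @param panel a [genotype_panel()]
#' @param dir output directory (created if absent)
#' @return invisibly, the three file paths
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "genotype_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gpath <- file.path(dir, "genotypes.tsv")
  mpath <- file.path(dir, "markers.tsv")
  spath <- file.path(dir, "samples.tsv")
  gt <- data.frame(sample_id = panel$samples$sample_id,
                   panel$genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(gt, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  mk <- panel$markers
  mk$chromosome <- ifelse(mk$chromosome == "unassigned", "0", mk$chromosome)
  utils::write.table(mk[, c("marker_id", "chromosome", "scaffold_id", "position_bp")],
                     mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$samples[, c("sample_id", "line_id", "vigor_class")],
                     spath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genotypes = gpath, markers = mpath, samples = spath))
}

#' Subset a genotype panel by samples and/or markers
#'
#' @param panel a [genotype_panel()]
#' @param samples sample ids or indices to keep (default all)
#' @param markers marker ids or indices to keep (default all)
#' @return a new [genotype_panel()] with call rates and MAF recomputed
#' @export
subset_panel <- function(panel, samples = NULL, markers = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  si <- if (is.null(samples)) seq_len(nrow(panel$genotypes)) else {
    if (is.character(samples)) match(samples, panel$samples$sample_id) else samples
  }
  mi <- if (is.null(markers)) seq_len(ncol(panel$genotypes)) else {
    if (is.character(markers)) match(markers, panel$markers$marker_id) else markers
  }
  if (anyNA(si)) stop("unknown sample id(s) in subset")
  if (anyNA(mi)) stop("unknown marker id(s) in subset")
  if (length(si) == 0L || length(mi) == 0L) stop("empty panel after subset")
  genotype_panel(panel$genotypes[si, mi, drop = FALSE],
                 panel$markers[mi, setdiff(names(panel$markers), c("call_rate", "maf")), drop = FALSE],
                 panel$samples[si, setdiff(names(panel$samples), "call_rate"), drop = FALSE])
}
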