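#!/usr/bin/env Rscript
# Marker and sample editing, then LD-based imputation of the surviving panel:
# duplicates out first, then markers at call rate <= 85%, then (after
# recomputing allele frequencies) markers at MAF <= 2.5%.

library(vigorclass)

panel <- load_genotypes("results/data/genotypes.tsv", "table",
                        map_path = "results/data/markers.tsv",
                        sample_path = "results/data/samples.tsv")
qc <- qc_filter(panel, max_snp_missing = 0.15, min_maf = 0.025)
print(qc$report)

imputed <- impute_missing(qc$panel, k = 5, min_r2 = 0.1)
n_filled <- nrow(attr(imputed, "imputed_cells"))
cat("\nImputed", n_filled, "missing genotypes (",
    sum(attr(imputed, "imputed_cells")$method == "ld_regression"),
    "by scaffold LD regression,",
    sum(attr(imputed, "imputed_cells")$method == "mode"), "by modal fallback)\n")

write_panel(imputed, "results/imputed")
utils::write.table(qc$report$removed_markers, "results/qc_removed_markers.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(qc$report$removed_samples, "results/qc_removed_samples.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
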