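#!/usr/bin/env Rscript
# Step 6: genomic context of the clock CpGs. Classify each clock site by
# CpG density (island / 2 kb shore / outside) and genic context (promoter
# within +/-2 kb of a TSS > exon > intron > intergenic), summarise the
# direction of age-related methylation change per context, and test the
# density trend of the per-site age correlations by one-way ANOVA.

source("analysis/00_config.R")

coefs <- read.table(file.path(RES_DIR, "clock_coefficients.tsv"), sep = "\t",
                    header = TRUE)
islands <- read_intervals(file.path(FIX_DIR, "synthetic_islands.bed"), "bed")
genes <- read_intervals(file.path(FIX_DIR, "synthetic_genes.bed12"), "bed12")

annotated <- annotate_clock_sites(coefs[, c("site", "r")], islands, genes)
sm <- summarize_by_context(annotated)

cat("clock sites by CpG density:\n")
print(sm$density_table, row.names = FALSE)
cat("clock sites by genic context:\n")
print(sm$genic_table, row.names = FALSE)
if (is.finite(sm$anova$f)) {
  cat(sprintf("ANOVA of age correlation across density groups: F = %.2f, p = %.3g\n",
              sm$anova$f, sm$anova$p))
}
write.table(annotated, file.path(RES_DIR, "clock_site_context.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sm$density_table, file.path(RES_DIR, "context_density_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sm$genic_table, file.path(RES_DIR, "context_genic_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
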