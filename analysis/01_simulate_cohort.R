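#!/usr/bin/env Rscript
# Step 1: simulate the longitudinal RRBS cohort with known per-site truth
# and write it to disk in the same formats a sequencing run would produce
# (one Bismark-style coverage file per sample + metadata TSV), plus a
# synthetic CpG-island / gene-model annotation for the context analysis.

source("analysis/00_config.R")

spec <- study_spec()
co <- simulate_cohort(spec)
fx <- write_fixture(co, FIX_DIR)

# anchor the synthetic islands/genes on simulated CpG positions (RRBS
# enriches CpG-dense regions), half of them on age-associated sites so the
# context analysis has both populated islands and a density contrast
set.seed(SEED)
age_sites <- co$truth[co$truth$klass %in% c("age_up", "age_down"),
                      c("chrom", "pos")]
anchors <- rbind(age_sites[sample.int(nrow(age_sites), 100), ],
                 co$truth[sample.int(nrow(co$truth), 100), c("chrom", "pos")])
ann <- simulate_annotation(n_islands = 200, n_genes = 60, sites = anchors,
                           seed = SEED)
# islands as BED3 (0-based half-open on disk), genes as BED12
writeLines(sprintf("%s\t%d\t%d", ann$islands$chrom, ann$islands$start - 1L,
                   ann$islands$end),
           file.path(FIX_DIR, "synthetic_islands.bed"))
bed12 <- vapply(seq_len(nrow(ann$genes)), function(i) {
  g <- ann$genes[i, ]
  ex <- g$exons[[1]]
  paste(g$chrom, g$start - 1L, g$end, g$gene_id, 0L, g$strand,
        g$start - 1L, g$end, "0", nrow(ex),
        paste0(paste(ex$end - ex$start + 1L, collapse = ","), ","),
        paste0(paste(ex$start - g$start, collapse = ","), ","),
        sep = "\t")
}, "")
writeLines(bed12, file.path(FIX_DIR, "synthetic_genes.bed12"))

cat(sprintf("cohort: %d individuals, %d samples, %d sites\n",
            spec$n_individuals, nrow(co$samples), spec$n_sites))
cat(sprintf("age range sampled: %.2f - %.2f years; %d longitudinal individuals\n",
            min(co$samples$age_years), max(co$samples$age_years),
            sum(table(co$samples$individual_id) > 1)))
cat(sprintf("planted age-associated sites: %d (%d up, %d down)\n",
            sum(co$truth$klass %in% c("age_up", "age_down")),
            sum(co$truth$klass == "age_up"), sum(co$truth$klass == "age_down")))
cat("fixture written under", FIX_DIR, "\n")
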