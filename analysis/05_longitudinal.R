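#!/usr/bin/env Rscript
# Step 5: within-individual DNAm-age trajectories. Keep each repeatedly
# sampled individual's first and last samples, drop near-duplicate pairs
# (< 1 day apart), and test whether DNAm age increases over elapsed time
# (one-sided one-sample t). The published sampling-age table is run through
# the same extraction as a worked arithmetic check.

source("analysis/00_config.R")

pred <- read.table(file.path(RES_DIR, "loiocv_predictions.tsv"), sep = "\t",
                   header = TRUE, colClasses = c(individual_id = "character"))

pairs <- filter_pairs(extract_first_last(pred), min_interval = 1 / 365.25)
res <- test_delta(pairs)
cat(sprintf("longitudinal pairs: %d (intervals %.2f-%.2f years, mean %.2f)\n",
            nrow(pairs), min(pairs$interval), max(pairs$interval),
            mean(pairs$interval)))
cat(sprintf("delta DNAm age: mean %.2f years; %d increased / %d decreased\n",
            res$mean_delta, res$n_increase, res$n_decrease))
cat(sprintf("one-sided t-test: t = %.2f, df = %d, p = %.3g\n",
            res$t, res$df, res$p))
write.table(pairs, file.path(RES_DIR, "longitudinal_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tab <- elephant_longitudinal_ages()
cat(sprintf("published table: %d rows; %d printed interval(s) disagree with the ages\n",
            nrow(tab), sum(!tab$consistent)))
print(tab[!tab$consistent, c("ind_id", "age_first", "age_last",
                             "interval_printed", "interval_recomputed")],
      row.names = FALSE)
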