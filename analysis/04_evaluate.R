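#!/usr/bin/env Rscript
# Step 4: score the assembled cross-validated predictions (MAE, r, R2,
# lifespan-relative error), contrast DNAm age across the five life stages
# (ANOVA + pairwise Welch + compact letters), project the clock-site
# methylation by PCA, and test for sex effects site-wise and on the
# delta-age residuals.

source("analysis/00_config.R")

meta <- read_metadata(file.path(FIX_DIR, "metadata.tsv"))
pred <- read.table(file.path(RES_DIR, "loiocv_predictions.tsv"), sep = "\t",
                   header = TRUE, colClasses = c(individual_id = "character"))
imp <- read.table(file.path(RES_DIR, "imputed_ratios.tsv"), sep = "\t",
                  header = TRUE, check.names = FALSE)
ratios <- as.matrix(imp[, -1]); rownames(ratios) <- imp$site
coefs <- read.table(file.path(RES_DIR, "clock_coefficients.tsv"), sep = "\t",
                    header = TRUE)

m <- compute_metrics(pred, max_lifespan = 79.6)
print(m)
cat(sprintf("age acceleration: SD of delta-age residuals = %.2f years\n",
            sd(delta_age_residuals(pred))))

cls <- compare_age_classes(pred)
cat(sprintf("life-stage ANOVA: F = %.2f (df %d, %d), p = %.3g\n",
            cls$anova$f, cls$anova$df[1], cls$anova$df[2], cls$anova$p))
cat("compact letters:",
    paste(names(cls$letters), cls$letters, sep = "=", collapse = "  "), "\n")
write.table(data.frame(class = names(cls$group_means),
                       mean_dnam_age = as.numeric(cls$group_means),
                       letters = cls$letters[names(cls$group_means)]),
            file.path(RES_DIR, "age_class_means.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

norm <- rank_normal(ratios[, pred$sample_id])
pc <- pca_project(norm[coefs$site, , drop = FALSE])
cat(sprintf("PCA of clock sites: PC1 %.1f%% of variance, |r|(PC1, age) = %.3f\n",
            100 * pc$var_frac[1], abs(cor(pc$scores[, 1], pred$age_years))))
write.table(data.frame(sample_id = pred$sample_id, pc$scores[, 1:3],
                       age_years = pred$age_years),
            file.path(RES_DIR, "pca_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sx <- sitewise_sex_model(norm[coefs$site, , drop = FALSE], pred)
if (!sx$skipped) {
  cat(sprintf("sex effects: %d of %d clock sites flagged at FDR < 0.05\n",
              sx$n_flagged, nrow(sx$table)))
  cat(sprintf("delta-age ~ sex: p = %.3g; + age adjustment: p = %.3g\n",
              sx$delta_sex_p, sx$delta_sex_p_age_adj))
  write.table(sx$table, file.path(RES_DIR, "sitewise_sex_model.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
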