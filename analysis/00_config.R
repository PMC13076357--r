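# Shared settings for the analysis drivers. Run the scripts in order from
# the repository root:  Rscript analysis/01_simulate_cohort.R  etc.
# Every step's computation lives in the methclock package; these scripts
# only orchestrate and record results.

library(methclock)

SEED <- 20260901
FIX_DIR <- "results/fixtures"
RES_DIR <- "results"

study_spec <- function(seed = SEED) {
  # scaled-down study conditions: 30 individuals, ~80 longitudinal blood
  # samples over ages 0-56, 20,000 CpG sites of which 300 drift with age
  cohort_spec(n_individuals = 30, n_sites = 20000, p_age = 300 / 20000,
              slope_range = c(0.03, 0.08), sigma_site = 0.3,
              coverage_mean = 30, age_profile = "elephant", seed = seed)
}

dir.create(FIX_DIR, showWarnings = FALSE, recursive = TRUE)
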