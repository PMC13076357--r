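# Shared fixture builders. Everything is generated in code at test time.

write_cov_lines <- function(df, path) {
  # independent text writer (not write_coverage_file) for parser oracles
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d", df$chrom, df$pos, df$pos,
                   format(df$pct), df$meth, df$unmeth)
  writeLines(lines, path)
  path
}

random_cov_df <- function(n, seed) {
  set.seed(seed)
  pos <- sort(sample.int(1e6, n))
  meth <- rbinom(n, 40, 0.6)
  unmeth <- rbinom(n, 40, 0.4)
  tot <- meth + unmeth
  data.frame(chrom = "chr1", pos = pos,
             pct = ifelse(tot > 0, 100 * meth / pmax(tot, 1), 0),
             meth = meth, unmeth = unmeth)
}

tiny_metadata <- function(ids, ind = ids, sex = rep("F", length(ids)),
                          age = seq_along(ids)) {
  data.frame(sample_id = ids, individual_id = ind, sex = sex,
             age_years = age, stringsAsFactors = FALSE)
}

# memoised scaled-down study cohort shared by the end-to-end checks
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (!is.null(.acceptance_cache$cohort)) return(.acceptance_cache$cohort)
  spec <- cohort_spec(n_individuals = 30, n_sites = 20000, p_age = 300 / 20000,
                      slope_range = c(0.03, 0.08), sigma_site = 0.3,
                      coverage_mean = 30, seed = 20260901)
  co <- simulate_cohort(spec)
  fl <- filter_sites(co$dataset)
  ratios <- impute_knn(get_ratios(fl$dataset))
  .acceptance_cache$cohort <- list(spec = spec, cohort = co, filtered = fl,
                                   ratios = ratios)
  .acceptance_cache$cohort
}

acceptance_loiocv <- function() {
  if (!is.null(.acceptance_cache$cv)) return(.acceptance_cache$cv)
  ac <- acceptance_cohort()
  norm <- rank_normal(ac$ratios)
  ages <- ac$cohort$samples$age_years
  sel <- select_features(norm, ages, threshold = 0.5)
  gs <- grid_search_alpha(t(norm[sel$site, , drop = FALSE]), ages,
                          alpha_grid = seq(0, 1, by = 0.1),
                          groups = ac$cohort$samples$individual_id, seed = 7)
  cv <- loiocv(ac$ratios, ac$cohort$samples, alpha = gs$alpha, lambda = "cv",
               selection_mode = "paper", seed = 7)
  .acceptance_cache$cv <- list(selection = sel, grid = gs, cv = cv)
  .acceptance_cache$cv
}
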