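#' Specification of a synthetic RRBS cohort
#'
#' Defines the generative conditions for a longitudinal blood-methylation
#' cohort: a zoo-style population of long-lived animals sampled repeatedly
#' over years, with a minority of CpG sites drifting with age on the logit
#' scale, constitutively hyper-/hypomethylated sites destined for removal by
#' filtering, negative-binomial read coverage and sparse missingness.
#'
#' Per-site classes: `age_up` / `age_down` (methylation logit-linear in age
#' with slope `+|beta1|` / `-|beta1|`), `const_high` (baseline ratio > 0.9),
#' `const_low` (< 0.1), and `null` (age-independent, moderate methylation).
#' The baseline methylation of null and age sites is drawn from a Beta
#' distribution targeting `target_mean_meth`; age-site intercepts are centred
#' at the cohort's mid-age so trajectories stay inside the dynamic range.
#'
#' @param n_individuals Number of animals.
#' @param n_sites Number of CpG sites.
#' @param p_age Proportion of age-associated sites (split evenly between
#'   hyper- and hypomethylating).
#' @param p_const_high,p_const_low Proportions of constitutive sites.
#' @param age_range Baseline age range in years (uniform draw, or the
#'   class-count mixture when `age_profile = "elephant"`).
#' @param age_profile `"uniform"`, or `"elephant"` to draw baseline ages from
#'   the study population's life-stage mixture (calf/juvenile/subadult/adult/
#'   senior weighted 7/4/41/30/9).
#' @param longitudinal_frac Fraction of individuals sampled repeatedly.
#' @param samples_per_ind Range (min, max) of samples per longitudinal
#'   individual.
#' @param interval_range Range of the gap between consecutive samples, years.
#' @param slope_range Range of |beta1|, logit units per year.
#' @param sigma_site Residual SD of the per-observation logit noise.
#' @param coverage_mean,coverage_size Negative-binomial read-depth mean and
#'   size (dispersion) per site/sample.
#' @param missing_prob Probability that an observation is dropped (total
#'   reads forced to 0) on top of NB zeros.
#' @param target_mean_meth Target global mean methylation ratio of
#'   moderate-methylation sites.
#' @param p_female Probability an individual is female.
#' @param seed Integer seed; all randomness flows from it through
#'   per-operation substreams, so a fixed seed gives byte-identical cohorts.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals = 30L,
                        n_sites = 100000L,
                        p_age = 0.05,
                        p_const_high = 0.05,
                        p_const_low = 0.05,
                        age_range = c(0, 56),
                        age_profile = c("uniform", "elephant"),
                        longitudinal_frac = 0.7,
                        samples_per_ind = c(2L, 5L),
                        interval_range = c(0.5, 5),
                        slope_range = c(0.03, 0.08),
                        sigma_site = 0.3,
                        coverage_mean = 30,
                        coverage_size = 5,
                        missing_prob = 0.02,
                        target_mean_meth = 0.66,
                        p_female = 0.9,
                        seed = 1L) {
  age_profile <- match.arg(age_profile)
  spec <- list(n_individuals = as.integer(n_individuals),
               n_sites = as.integer(n_sites),
               p_age = p_age, p_const_high = p_const_high,
               p_const_low = p_const_low,
               age_range = age_range, age_profile = age_profile,
               longitudinal_frac = longitudinal_frac,
               samples_per_ind = as.integer(samples_per_ind),
               interval_range = interval_range,
               slope_range = slope_range, sigma_site = sigma_site,
               coverage_mean = coverage_mean, coverage_size = coverage_size,
               missing_prob = missing_prob,
               target_mean_meth = target_mean_meth,
               p_female = p_female, seed = as.integer(seed))
  probs <- c(spec$p_age, spec$p_const_high, spec$p_const_low)
  if (any(probs < 0) || any(probs > 1) || sum(probs) > 1) {
    stop("class proportions must lie in [0,1] and sum to at most 1")
  }
  if (spec$n_individuals < 1L || spec$n_sites < 1L) {
    stop("n_individuals and n_sites must be positive")
  }
  if (spec$longitudinal_frac < 0 || spec$longitudinal_frac > 1) {
    stop("longitudinal_frac must lie in [0,1]")
  }
  if (diff(spec$age_range) < 0 || diff(spec$interval_range) < 0 ||
      diff(spec$slope_range) < 0 || spec$samples_per_ind[1L] < 2L) {
    stop("ranges must be non-decreasing; samples_per_ind minimum is 2")
  }
  class(spec) <- "cohort_spec"
  spec
}

# Deterministic substream: every generator operation reseeds from
# (seed, op-name) so partial re-runs reproduce exactly.
substream_seed <- function(seed, op) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Life-stage mixture of the study population (samples per class
# calf/juvenile/subadult/adult/senior = 7/4/41/30/9).
elephant_age_mixture <- function(n) {
  lo <- c(0, 1, 5, 20, 50)
  hi <- c(1, 5, 20, 50, 56)
  w <- c(7, 4, 41, 30, 9)
  cls <- sample.int(5L, n, replace = TRUE, prob = w / sum(w))
  stats::runif(n, lo[cls], hi[cls])
}

#' Generate the individuals and sampling design of a synthetic cohort
#'
#' Each individual gets a baseline age (uniform over `age_range`, or the
#' elephant life-stage mixture); a `longitudinal_frac` subset is sampled
#' repeatedly at cumulative uniform intervals, the rest once. Sex is assigned
#' with probability `p_female`.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame of sample records (`sample_id`, `individual_id`,
#'   `sex`, `age_years`), ordered by individual then age.
#' @export
generate_individuals <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(substream_seed(spec$seed, "individuals"))
  n <- spec$n_individuals
  base_age <- if (spec$age_profile == "elephant") elephant_age_mixture(n) else
    stats::runif(n, spec$age_range[1L], spec$age_range[2L])
  sex <- ifelse(stats::runif(n) < spec$p_female, "F", "M")
  n_long <- round(spec$longitudinal_frac * n)
  long_idx <- if (n_long > 0) sample.int(n, n_long) else integer(0)
  n_samp <- rep(1L, n)
  if (n_long > 0) {
    n_samp[long_idx] <- sample(seq(spec$samples_per_ind[1L],
                                   spec$samples_per_ind[2L]),
                               n_long, replace = TRUE)
  }
  recs <- lapply(seq_len(n), function(i) {
    gaps <- if (n_samp[i] > 1L)
      stats::runif(n_samp[i] - 1L, spec$interval_range[1L], spec$interval_range[2L])
    else numeric(0)
    ages <- base_age[i] + c(0, cumsum(gaps))
    data.frame(sample_id = sprintf("ind%02d_s%d", i, seq_len(n_samp[i])),
               individual_id = sprintf("ind%02d", i),
               sex = sex[i], age_years = ages,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# Location of a Beta(nu*t, nu*(1-t)) baseline targeting the global mean.
draw_baseline <- function(n, target, nu = 8) {
  p <- stats::rbeta(n, nu * target, nu * (1 - target))
  pmin(pmax(p, 0.105), 0.895)  # keep moderate sites clear of the filter bounds
}

#' Generate methylation counts and per-site ground truth
#'
#' For sample i at site j the latent methylation probability is
#' `inv_logit(beta0_j + beta1_j * age_i + e_ij)` with
#' `e_ij ~ Normal(0, sigma_site)`; total reads are negative-binomial
#' (`coverage_mean`, `coverage_size`), zeroed with `missing_prob`; methylated
#' reads are binomial in the latent probability.
#'
#' @param spec A [cohort_spec()].
#' @param samples Sample records from [generate_individuals()].
#' @return A list with `dataset` (a `MethylationDataset`) and `truth`
#'   (data.frame: `chrom`, `pos`, `klass`, `beta0`, `beta1`, `sigma_site`).
#' @export
generate_methylation <- function(spec, samples) {
  stopifnot(inherits(spec, "cohort_spec"), nrow(samples) > 0)
  set.seed(substream_seed(spec$seed, "methylation"))
  m <- spec$n_sites
  n <- nrow(samples)

  n_age <- round(spec$p_age * m)
  n_up <- ceiling(n_age / 2)
  n_down <- n_age - n_up
  n_ch <- round(spec$p_const_high * m)
  n_cl <- round(spec$p_const_low * m)
  klass <- sample(c(rep("age_up", n_up), rep("age_down", n_down),
                    rep("const_high", n_ch), rep("const_low", n_cl),
                    rep("null", m - n_age - n_ch - n_cl)))

  beta0 <- numeric(m)
  beta1 <- numeric(m)
  mod <- klass %in% c("null", "age_up", "age_down")
  beta0[mod] <- logit(draw_baseline(sum(mod), spec$target_mean_meth))
  beta0[klass == "const_high"] <- logit(stats::runif(n_ch, 0.93, 0.99))
  beta0[klass == "const_low"] <- logit(stats::runif(n_cl, 0.01, 0.07))
  is_up <- klass == "age_up"
  is_down <- klass == "age_down"
  beta1[is_up] <- stats::runif(sum(is_up), spec$slope_range[1L], spec$slope_range[2L])
  beta1[is_down] <- -stats::runif(sum(is_down), spec$slope_range[1L], spec$slope_range[2L])
  # centre age trajectories at the cohort mid-age so they stay in range
  age_mid <- mean(spec$age_range)
  beta0[is_up | is_down] <- beta0[is_up | is_down] - beta1[is_up | is_down] * age_mid

  # site coordinates: spread over 28 chromosomes at random increasing positions
  chrom_n <- pmin(28L, m)
  chrom_of <- sort(sample.int(chrom_n, m, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(m), chrom_of), function(ix)
    sort(sample.int(5e7L, length(ix)))), use.names = FALSE)
  sites <- data.frame(chrom = sprintf("chr%02d", chrom_of), pos = pos,
                      stringsAsFactors = FALSE)
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  klass <- klass[o]; beta0 <- beta0[o]; beta1 <- beta1[o]
  rownames(sites) <- NULL

  ages <- samples$age_years
  eta <- outer(beta1, ages) + beta0 +
    matrix(stats::rnorm(m * n, 0, spec$sigma_site), m, n)
  p <- inv_logit(eta)
  total <- matrix(stats::rnbinom(m * n, mu = spec$coverage_mean,
                                 size = spec$coverage_size), m, n)
  if (spec$missing_prob > 0) {
    total[matrix(stats::runif(m * n) < spec$missing_prob, m, n)] <- 0L
  }
  meth <- matrix(stats::rbinom(m * n, total, p), m, n)
  storage.mode(total) <- "integer"
  storage.mode(meth) <- "integer"

  truth <- data.frame(sites, klass = klass, beta0 = beta0, beta1 = beta1,
                      sigma_site = spec$sigma_site, stringsAsFactors = FALSE)
  list(dataset = methylation_dataset(sites, samples, meth, total),
       truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: [generate_individuals()] then
#' [generate_methylation()].
#'
#' @param spec A [cohort_spec()].
#' @return List with `dataset`, `truth`, `samples` and the echoed `spec`.
#' @export
simulate_cohort <- function(spec) {
  samples <- generate_individuals(spec)
  gm <- generate_methylation(spec, samples)
  list(dataset = gm$dataset, truth = gm$truth, samples = samples, spec = spec)
}

#' Analytic attainable age correlation of planted sites
#'
#' The Pearson correlation a site's observed ratio can reach with age, from
#' the generative model: signal SD `|beta1| * sd(age)` on the logit scale
#' against residual noise `sigma_site` plus the delta-method binomial logit
#' variance `1 / (coverage * p * (1 - p))` at the site's mid-age methylation.
#' Used to decide which planted sites are recoverable at a given |r| cutoff.
#'
#' @param truth Truth table from [generate_methylation()].
#' @param samples Sample records (ages actually generated).
#' @param spec The [cohort_spec()] used.
#' @return Numeric vector, one signed r per site (0 for non-age sites).
#' @export
attainable_correlation <- function(truth, samples, spec) {
  sd_age <- stats::sd(samples$age_years)
  p_mid <- inv_logit(truth$beta0 + truth$beta1 * mean(samples$age_years))
  v_binom <- 1 / (spec$coverage_mean * p_mid * (1 - p_mid))
  sig <- truth$beta1 * sd_age
  r <- sig / sqrt(sig^2 + spec$sigma_site^2 + v_binom)
  r[!(truth$klass %in% c("age_up", "age_down"))] <- 0
  r
}

#' Write a cohort to disk as a fixture
#'
#' Emits one Bismark-style coverage file per sample, a metadata TSV, the
#' per-site truth TSV and a YAML echo of the spec (including the seed).
#' Reading the files back through [assemble_dataset()] reproduces the dataset
#' exactly, and a fixed seed gives byte-identical files.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- cohort$dataset
  cov_paths <- character(nrow(ds$samples))
  names(cov_paths) <- ds$samples$sample_id
  for (j in seq_len(nrow(ds$samples))) {
    id <- ds$samples$sample_id[j]
    counts <- data.frame(chrom = ds$sites$chrom, pos = ds$sites$pos,
                         methylated = ds$meth[, j], total = ds$total[, j])
    counts <- counts[counts$total > 0, , drop = FALSE]  # unobserved sites omitted
    cov_paths[j] <- file.path(out_dir, paste0(id, ".cov"))
    write_coverage_file(counts, cov_paths[j])
  }
  meta_path <- file.path(out_dir, "metadata.tsv")
  utils::write.table(ds$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(cohort$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spec_path <- file.path(out_dir, "spec.yaml")
  yaml::write_yaml(unclass(cohort$spec), spec_path)
  invisible(list(coverage = cov_paths, metadata = meta_path,
                 truth = truth_path, spec = spec_path))
}

#' Simulate CpG-island and gene-model annotation
#'
#' Synthetic genomic context for exercising the annotation module:
#' non-overlapping CpG islands (BED-style intervals) and strand-aware gene
#' models with exon blocks, on the same chromosome naming scheme as
#' [generate_methylation()]. When a table of CpG `sites` is supplied,
#' islands and genes are anchored on randomly chosen sites — mirroring how
#' RRBS enriches CpG-dense regions, so a realistic share of sites falls
#' inside islands, shores and gene bodies; otherwise intervals are placed
#' uniformly at random.
#'
#' @param n_islands,n_genes Counts to simulate.
#' @param chrom_n Number of chromosomes.
#' @param chrom_len Chromosome length, bp.
#' @param sites Optional data.frame (`chrom`, `pos`) to anchor intervals on.
#' @param seed Integer seed.
#' @return List with `islands` (data.frame `chrom`, `start`, `end`, 1-based
#'   inclusive) and `genes` (data.frame as returned by
#'   [read_intervals()] with `kind = "bed12"`).
#' @export
simulate_annotation <- function(n_islands = 50L, n_genes = 20L,
                                chrom_n = 28L, chrom_len = 5e7L,
                                sites = NULL, seed = 1L) {
  set.seed(substream_seed(seed, "annotation"))
  if (!is.null(sites)) {
    anchor <- sites[sample.int(nrow(sites), min(n_islands, nrow(sites))), ]
    half <- as.integer(stats::runif(nrow(anchor), 100, 1000))
    islands <- data.frame(chrom = anchor$chrom,
                          start = pmax(anchor$pos - half, 1L),
                          end = anchor$pos + half,
                          stringsAsFactors = FALSE)
  } else {
    isl_chr <- sample.int(chrom_n, n_islands, replace = TRUE)
    isl_start <- as.integer(stats::runif(n_islands, 1e4, chrom_len - 1e4))
    isl_len <- as.integer(stats::runif(n_islands, 200, 2000))
    islands <- data.frame(chrom = sprintf("chr%02d", isl_chr),
                          start = isl_start, end = isl_start + isl_len,
                          stringsAsFactors = FALSE)
  }
  # drop overlaps within 4 kb so shores never collide ambiguously
  islands <- islands[order(islands$chrom, islands$start), , drop = FALSE]
  keep <- !logical(nrow(islands))
  for (i in seq_len(nrow(islands))[-1]) {
    j <- max(which(keep[seq_len(i - 1L)]))
    if (islands$chrom[i] == islands$chrom[j] &&
        islands$start[i] <= islands$end[j] + 4001L) keep[i] <- FALSE
  }
  islands <- islands[keep, , drop = FALSE]
  rownames(islands) <- NULL

  if (!is.null(sites)) {
    ganchor <- sites[sample.int(nrow(sites), min(n_genes, nrow(sites))), ]
    g_len <- as.integer(stats::runif(nrow(ganchor), 5e3, 1e5))
    g_start <- pmax(as.integer(ganchor$pos - stats::runif(nrow(ganchor), 0, 1) * g_len), 1L)
    g_chr_name <- ganchor$chrom
    n_genes <- nrow(ganchor)
  } else {
    g_chr <- sample.int(chrom_n, n_genes, replace = TRUE)
    g_start <- as.integer(stats::runif(n_genes, 1e4, chrom_len - 2e5))
    g_len <- as.integer(stats::runif(n_genes, 5e3, 1e5))
    g_chr_name <- sprintf("chr%02d", g_chr)
  }
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  exons <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    n_ex <- sample(2:6, 1L)
    cuts <- sort(sample.int(g_len[i] - 2L, 2L * (n_ex - 1L)) )
    b <- matrix(c(0L, cuts, g_len[i] - 1L), ncol = 2L, byrow = TRUE)
    exons[[i]] <- data.frame(start = g_start[i] + b[, 1L],
                             end = g_start[i] + b[, 2L])
  }
  genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
                      chrom = g_chr_name,
                      start = g_start, end = g_start + g_len - 1L,
                      strand = strand,
                      tss = ifelse(strand == "+", g_start, g_start + g_len - 1L),
                      stringsAsFactors = FALSE)
  genes$exons <- exons
  list(islands = islands, genes = genes)
}
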