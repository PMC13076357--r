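#' Filter CpG sites on coverage, mean methylation and missingness
#'
#' Applies the three standard RRBS site filters, in any order (the result is
#' rule-order independent):
#'
#' * mean coverage depth across all samples (a missing entry counts as 0
#'   reads in the mean) at least `min_mean_cov`;
#' * mean methylation ratio across non-missing samples inside `meth_bounds`
#'   (inclusive), removing constitutively hyper-/hypomethylated sites;
#' * fraction of missing entries strictly below `max_missing_frac`
#'   (a fraction equal to the bound excludes the site). With
#'   `missing_unit = "individual"` the fraction is computed over individuals,
#'   an individual counting as missing when none of its samples covers the
#'   site.
#'
#' @param dataset A `MethylationDataset` (must carry read counts).
#' @param min_mean_cov Minimum mean coverage depth (default 5x).
#' @param meth_bounds Inclusive bounds on the mean methylation ratio.
#' @param max_missing_frac Exclusive upper bound on the missing fraction.
#' @param missing_unit Unit over which the missing fraction is computed.
#' @return A list: `dataset` (the filtered `MethylationDataset`) and `report`
#'   (class `FilterReport`: per-rule failure counts and site keys).
#' @export
filter_sites <- function(dataset, min_mean_cov = 5, meth_bounds = c(0.1, 0.9),
                         max_missing_frac = 0.05,
                         missing_unit = c("sample", "individual")) {
  if (!inherits(dataset, "MethylationDataset") || is.null(dataset$total)) {
    stop("filter_sites needs a MethylationDataset with read counts")
  }
  missing_unit <- match.arg(missing_unit)
  total <- dataset$total
  ratios <- get_ratios(dataset)
  n_samples <- ncol(total)

  mean_cov <- rowMeans(total)  # missing entries are total == 0
  fail_cov <- mean_cov < min_mean_cov

  mean_meth <- rowMeans(ratios, na.rm = TRUE)
  fail_meth <- is.nan(mean_meth) | mean_meth < meth_bounds[1L] |
    mean_meth > meth_bounds[2L]

  if (missing_unit == "sample") {
    miss_frac <- rowMeans(total == 0)
  } else {
    ind <- dataset$samples$individual_id
    obs_by_ind <- vapply(split(seq_len(n_samples), ind), function(cols) {
      rowSums(total[, cols, drop = FALSE] > 0) > 0
    }, logical(nrow(total)))
    miss_frac <- 1 - rowMeans(obs_by_ind)
  }
  fail_miss <- miss_frac >= max_missing_frac

  keep <- !(fail_cov | fail_meth | fail_miss)
  keys <- rownames(total)
  report <- structure(list(
    n_input_sites = nrow(total),
    n_fail_coverage = sum(fail_cov),
    n_fail_meanmeth = sum(fail_meth),
    n_fail_missing = sum(fail_miss),
    n_retained = sum(keep),
    fail_coverage_sites = keys[fail_cov],
    fail_meanmeth_sites = keys[fail_meth],
    fail_missing_sites = keys[fail_miss]
  ), class = "FilterReport")

  filtered <- methylation_dataset(dataset$sites[keep, , drop = FALSE],
                                  dataset$samples,
                                  dataset$meth[keep, , drop = FALSE],
                                  dataset$total[keep, , drop = FALSE])
  list(dataset = filtered, report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport: %d input sites, %d retained\n",
              x$n_input_sites, x$n_retained))
  cat(sprintf("  failed mean coverage : %d\n", x$n_fail_coverage))
  cat(sprintf("  failed mean methylation bounds: %d\n", x$n_fail_meanmeth))
  cat(sprintf("  failed missingness   : %d\n", x$n_fail_missing))
  invisible(x)
}

#' k-nearest-neighbour imputation of missing methylation ratios
#'
#' Each missing entry (site j, sample i) is replaced by the mean of sample
#' i's values at the `k` sites nearest to j, where nearness is Euclidean
#' distance over the samples where both sites are observed, restricted to
#' neighbour sites observed in sample i. Sites missing in at least half the
#' samples fall back to their own mean over observed samples. Observed
#' entries are never altered; imputed values are clipped to \[0, 1\].
#'
#' Distances are exhaustive (every pair of sites is considered), computed
#' blockwise via matrix products so cohorts of tens of thousands of sites
#' remain tractable.
#'
#' @param x Numeric matrix, sites x samples, `NA` marking missing.
#' @param k Number of neighbour sites (default 10).
#' @param chunk_size Query rows per distance block (memory/speed trade-off).
#' @return A complete matrix of the same shape.
#' @export
impute_knn <- function(x, k = 10L, chunk_size = 2000L) {
  stopifnot(is.matrix(x))
  if (k >= nrow(x)) stop("k must be smaller than the number of sites")
  if (!anyNA(x)) return(x)
  miss <- is.na(x)
  row_n_miss <- rowSums(miss)
  row_mean <- rowMeans(x, na.rm = TRUE)
  if (any(row_n_miss == ncol(x))) {
    stop("site(s) with no observed value at all cannot be imputed: ",
         paste(utils::head(rownames(x)[row_n_miss == ncol(x)], 5), collapse = ", "))
  }

  out <- x + 0  # force a copy; mutated in place by the C++ kernel
  # >= 50% missing: row-mean fallback
  fb <- which(row_n_miss * 2L >= ncol(x) & row_n_miss > 0L)
  for (j in fb) out[j, miss[j, ]] <- min(max(row_mean[j], 0), 1)

  query <- which(row_n_miss > 0L & row_n_miss * 2L < ncol(x))
  if (length(query) == 0L) return(out)

  W <- 1 - miss          # observed indicator
  X0 <- x
  X0[miss] <- 0
  S <- X0^2
  tW <- t(W); tS <- t(S); tX0 <- t(X0)

  for (start in seq(1L, length(query), by = chunk_size)) {
    idx <- query[start:min(start + chunk_size - 1L, length(query))]
    A <- S[idx, , drop = FALSE] %*% tW
    B <- W[idx, , drop = FALSE] %*% tS
    C <- X0[idx, , drop = FALSE] %*% tX0
    Nshare <- W[idx, , drop = FALSE] %*% tW
    d2 <- A + B - 2 * C
    d2[d2 < 0] <- 0
    d2[Nshare == 0] <- Inf
    d2[cbind(seq_along(idx), idx)] <- Inf  # a site is not its own neighbour
    knn_fill_chunk(out, x, d2, as.integer(idx), as.integer(k), row_mean)
  }
  out
}

#' Rank-based inverse-normal transform within each sample
#'
#' Replaces each sample's values by normal quantiles of their ranks over the
#' given site universe: `qnorm((r - a) / (n + 1 - 2a))` with `a = 3/8` for
#' `n <= 10` and `a = 1/2` otherwise (the `qqnorm` plotting-position
#' convention); tied values receive the mean of their ranks. Each sample is
#' transformed independently of every other sample, so the transform commutes
#' with sample subsetting and new samples can be normalised without touching
#' training data.
#'
#' @param x Complete numeric matrix, sites x samples.
#' @return Matrix of the same shape with attributes `normalization`
#'   (`"rank_normal_per_sample"`) and `site_universe` (the rownames the ranks
#'   were computed over).
#' @export
rank_normal <- function(x) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("rank_normal requires a complete matrix; impute first")
  n <- nrow(x)
  if (n < 2L) stop("at least 2 sites are required to rank-normalise")
  a <- if (n <= 10L) 3 / 8 else 0.5
  out <- apply(x, 2L, function(col) {
    stats::qnorm((rank(col, ties.method = "average") - a) / (n + 1 - 2 * a))
  })
  dimnames(out) <- dimnames(x)
  attr(out, "normalization") <- "rank_normal_per_sample"
  attr(out, "site_universe") <- rownames(x)
  out
}
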