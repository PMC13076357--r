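#' Relative prediction error against a species' maximum lifespan
#'
#' `100 * MAE / max_lifespan`, the conventional way to compare clock
#' accuracy across species with different lifespans. The default lifespan is
#' the maximum recorded for the Asian elephant, 79.6 years.
#'
#' @param mae Mean absolute error in years.
#' @param max_lifespan Maximum recorded lifespan in years.
#' @return Relative error in percent.
#' @export
relative_error <- function(mae, max_lifespan = 79.6) {
  100 * mae / max_lifespan
}

#' Accuracy metrics of age predictions
#'
#' Computes MAE, Pearson's r, R-squared and the lifespan-relative error of
#' DNAm-age predictions. R-squared is reported as the squared Pearson
#' correlation of predicted versus observed age (the pairing used by clock
#' studies); the variance-explained variant `1 - SSE/SST` is also returned,
#' labelled `r2_sse`.
#'
#' @param predictions Data.frame with columns `dnam_age` and `age_years`.
#' @param max_lifespan Lifespan used for the relative error (years).
#' @return List of class `EvaluationReport`: `n_samples`, `mae`,
#'   `pearson_r`, `r2`, `r2_sse`, `relative_error_pct`, `max_lifespan_used`.
#' @export
compute_metrics <- function(predictions, max_lifespan = 79.6) {
  stopifnot(all(c("dnam_age", "age_years") %in% names(predictions)))
  y <- predictions$age_years
  p <- predictions$dnam_age
  if (length(y) < 2L) stop("at least 2 predictions are required")
  if (stats::sd(y) == 0 || stats::sd(p) == 0) {
    stop("zero variance in predictions or ages; correlation is undefined")
  }
  mae <- mean(abs(p - y))
  r <- stats::cor(p, y)
  structure(list(n_samples = length(y), mae = mae, pearson_r = r, r2 = r^2,
                 r2_sse = 1 - sum((y - p)^2) / sum((y - mean(y))^2),
                 relative_error_pct = relative_error(mae, max_lifespan),
                 max_lifespan_used = max_lifespan),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("n = %d samples: MAE %.2f y | r %.3f | R2 %.3f | relative error %.2f%% (lifespan %.1f y)\n",
              x$n_samples, x$mae, x$pearson_r, x$r2,
              x$relative_error_pct, x$max_lifespan_used))
  invisible(x)
}

#' Epigenetic age-acceleration residuals
#'
#' Residuals of the ordinary least-squares regression of DNAm age on
#' chronological age (delta-age): positive values mark samples epigenetically
#' older than expected for their age. Mean zero by construction.
#'
#' @param predictions Data.frame with `dnam_age` and `age_years` (and
#'   optionally `sample_id` for naming).
#' @return Numeric vector of residuals, named by sample id when available.
#' @export
delta_age_residuals <- function(predictions) {
  if (nrow(predictions) < 3L) stop("at least 3 samples are required")
  if (stats::sd(predictions$age_years) == 0) {
    stop("chronological age is constant; the regression is undefined")
  }
  fit <- stats::lm(dnam_age ~ age_years, data = predictions)
  res <- stats::residuals(fit)
  names(res) <- if ("sample_id" %in% names(predictions)) predictions$sample_id
  res
}

#' Life-stage class of an age
#'
#' Maps ages to the five elephant life stages: calf `[0, 1)`, juvenile
#' `[1, 5)`, subadult `[5, 20)`, adult `[20, 50)`, senior `[50, Inf)`.
#' Boundaries are half-open on the left value (an exact 20.0 is an adult).
#'
#' @param age_years Non-negative ages in years (vectorised).
#' @return Factor with levels calf < juvenile < subadult < adult < senior.
#' @export
assign_age_class <- function(age_years) {
  if (any(age_years < 0)) stop("ages must be non-negative")
  cut(age_years, breaks = c(0, 1, 5, 20, 50, Inf), right = FALSE,
      labels = c("calf", "juvenile", "subadult", "adult", "senior"),
      ordered_result = TRUE)
}

# Compact letter display from a pairwise p-value matrix: groups sharing a
# letter are not significantly different. Maximal cliques of the
# non-significance graph, brute-forced (group counts here are tiny).
compact_letters <- function(pmat, groups, alpha = 0.05) {
  k <- length(groups)
  if (k == 1L) return(stats::setNames("a", groups))
  nsd <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    p <- c(pmat[groups[i], groups[j]], pmat[groups[j], groups[i]])
    p <- p[!is.na(p)]
    if (length(p) > 0 && min(p) < alpha) nsd[i, j] <- FALSE
  }
  cliques <- list()
  for (code in seq_len(2^k - 1L)) {
    members <- which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0)
    if (all(nsd[members, members])) {
      maximal <- TRUE
      for (extra in setdiff(seq_len(k), members)) {
        if (all(nsd[c(members, extra), c(members, extra)])) { maximal <- FALSE; break }
      }
      if (maximal) cliques[[length(cliques) + 1L]] <- members
    }
  }
  first <- vapply(cliques, min, 0L)
  cliques <- cliques[order(first)]
  letters_out <- stats::setNames(rep("", k), groups)
  for (ci in seq_along(cliques)) {
    letters_out[cliques[[ci]]] <- paste0(letters_out[cliques[[ci]]], letters[ci])
  }
  letters_out
}

#' Compare DNAm age across life-stage classes
#'
#' One-way ANOVA of DNAm age on age class, followed by pairwise Welch
#' t-tests with Benjamini-Hochberg adjustment and a compact-letter grouping
#' (groups sharing a letter are not separable at the 0.05 level). Classes
#' with fewer than 2 samples are dropped with a warning.
#'
#' @param predictions Data.frame with `dnam_age` and `age_years` (classes
#'   derived from chronological age), or an explicit `age_class` column.
#' @return List: `anova` (`f`, `df`, `p`), `group_means`, `pairwise`
#'   (BH-adjusted Welch p-value matrix), `letters`.
#' @export
compare_age_classes <- function(predictions) {
  cls <- if ("age_class" %in% names(predictions)) {
    factor(predictions$age_class)
  } else {
    assign_age_class(predictions$age_years)
  }
  cls <- droplevels(cls)
  small <- names(which(table(cls) < 2))
  if (length(small) > 0) {
    warning("dropping class(es) with < 2 samples: ", paste(small, collapse = ", "))
    keep <- !(cls %in% small)
    predictions <- predictions[keep, , drop = FALSE]
    cls <- droplevels(cls[keep])
  }
  if (nlevels(cls) < 2L) stop("need at least 2 classes with >= 2 samples")
  y <- predictions$dnam_age
  fit <- stats::aov(y ~ cls)
  an <- summary(fit)[[1L]]
  pw <- stats::pairwise.t.test(y, cls, p.adjust.method = "BH", pool.sd = FALSE)
  pmat <- pw$p.value
  full <- matrix(NA_real_, nlevels(cls), nlevels(cls),
                 dimnames = list(levels(cls), levels(cls)))
  full[rownames(pmat), colnames(pmat)] <- pmat
  list(anova = list(f = an$`F value`[1L], df = c(an$Df[1L], an$Df[2L]),
                    p = an$`Pr(>F)`[1L]),
       group_means = tapply(y, cls, mean),
       pairwise = full,
       letters = compact_letters(full, levels(cls)))
}

#' Principal component analysis of methylation profiles
#'
#' Centred, unit-scaled PCA (singular value decomposition) of samples over a
#' set of CpG sites, typically the clock sites. Zero-variance sites are
#' dropped with a warning. Component signs follow the convention that each
#' component's largest-magnitude loading is positive.
#'
#' @param x Numeric matrix, sites x samples.
#' @param scale Unit-scale the sites (default `TRUE`).
#' @return List: `scores` (samples x components), `loadings` (sites x
#'   components), `var_frac` (variance fractions, summing to 1).
#' @export
pca_project <- function(x, scale = TRUE) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 3L || nrow(x) < 2L) stop("need >= 3 samples and >= 2 sites")
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance site(s)", sum(sds == 0)))
    x <- x[sds > 0, , drop = FALSE]
  }
  pr <- stats::prcomp(t(x), center = TRUE, scale. = scale)
  flip <- vapply(seq_len(ncol(pr$rotation)), function(k) {
    pr$rotation[which.max(abs(pr$rotation[, k])), k] < 0
  }, logical(1L))
  pr$rotation[, flip] <- -pr$rotation[, flip]
  pr$x[, flip] <- -pr$x[, flip]
  list(scores = pr$x, loadings = pr$rotation,
       var_frac = pr$sdev^2 / sum(pr$sdev^2))
}

#' Site-wise sex effects at clock CpGs
#'
#' Per site, a linear model `methylation ~ DNAm age + sex + DNAm age x sex`;
#' the reported per-site p-value is the smaller of the sex main effect and
#' the interaction (which term is flagged), adjusted over sites by
#' Benjamini-Hochberg; `q < 0.05` flags a site. A companion Gaussian model of
#' the delta-age residuals on sex (and on sex plus age) is reported
#' alongside. If either sex has fewer than `min_per_sex` samples the analysis
#' is skipped with an explicit notice (single-sex or heavily skewed cohorts
#' cannot support it).
#'
#' All sites are fit in one pass through a shared design matrix (QR once,
#' per-site residual variances), so thousands of sites are cheap.
#'
#' @param x Numeric matrix, sites x samples (methylation at clock sites,
#'   normalised or raw ratios).
#' @param predictions Data.frame aligned with the columns of `x`, with
#'   `dnam_age`, `age_years` and `sex` (F/M; NA allowed, those samples are
#'   excluded).
#' @param fdr Flagging threshold on the BH-adjusted q-value.
#' @param min_per_sex Minimum samples per sex.
#' @return List: `skipped` (logical, with `reason` when `TRUE`), `table`
#'   (site, p_sex, p_interaction, p, term, q, flagged), `n_flagged`,
#'   `delta_sex_p` and `delta_sex_p_age_adj`.
#' @export
sitewise_sex_model <- function(x, predictions, fdr = 0.05, min_per_sex = 3L) {
  stopifnot(is.matrix(x), ncol(x) == nrow(predictions))
  keep <- !is.na(predictions$sex)
  x <- x[, keep, drop = FALSE]
  predictions <- predictions[keep, , drop = FALSE]
  n_sex <- table(factor(predictions$sex, levels = c("F", "M")))
  if (any(n_sex < min_per_sex)) {
    message(sprintf("sex analyses skipped: need >= %d samples of each sex (have F = %d, M = %d)",
                    min_per_sex, n_sex["F"], n_sex["M"]))
    return(list(skipped = TRUE,
                reason = "insufficient samples of one sex"))
  }
  male <- as.numeric(predictions$sex == "M")
  age <- predictions$dnam_age
  X <- cbind(1, age, male, age * male)
  n <- nrow(X); pcol <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < pcol) stop("degenerate design (collinear age and sex)")
  Y <- t(x)
  coefs <- qr.coef(qrX, Y)
  res <- Y - X %*% coefs
  df <- n - pcol
  sigma2 <- colSums(res^2) / df
  xtx_inv_diag <- diag(chol2inv(qr.R(qrX)))
  p_of <- function(row) {
    se <- sqrt(xtx_inv_diag[row] * sigma2)
    tt <- coefs[row, ] / se
    2 * stats::pt(-abs(tt), df)
  }
  p_sex <- p_of(3L)
  p_int <- p_of(4L)
  p_min <- pmin(p_sex, p_int)
  term <- ifelse(p_sex <= p_int, "sex", "interaction")
  q <- stats::p.adjust(p_min, method = "BH")
  tab <- data.frame(site = rownames(x), p_sex = p_sex, p_interaction = p_int,
                    p = p_min, term = term, q = q, flagged = !is.na(q) & q < fdr,
                    stringsAsFactors = FALSE, row.names = NULL)

  delta <- delta_age_residuals(predictions)
  d1 <- stats::glm(delta ~ sex, data = cbind(predictions, delta = delta))
  d2 <- stats::glm(delta ~ sex + age_years, data = cbind(predictions, delta = delta))
  p_d1 <- summary(d1)$coefficients["sexM", 4L]
  p_d2 <- summary(d2)$coefficients["sexM", 4L]
  list(skipped = FALSE, table = tab, n_flagged = sum(tab$flagged),
       delta_sex_p = p_d1, delta_sex_p_age_adj = p_d2)
}
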