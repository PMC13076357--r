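#' Age-stratified train/test split
#'
#' Bins ages into quantile bins and assigns a fixed fraction of each bin to
#' the training set, keeping the age distribution balanced across the split.
#' The total training size is exactly `round(train_frac * n)`: bins get the
#' floor of their share and the remainder goes to the bins with the largest
#' fractional parts. With `unit = "individual"` all samples of an individual
#' stay on one side (individuals are binned by their first-sample age).
#'
#' @param samples Sample records (`sample_id`, `individual_id`, `age_years`).
#' @param train_frac Fraction assigned to training, in (0, 1).
#' @param n_bins Number of age-quantile bins.
#' @param seed Integer seed for the within-bin draw.
#' @param unit Split unit: `"sample"` (repeated samples of an individual may
#'   straddle the split) or `"individual"` (leakage-free).
#' @return List with character vectors `train` and `test` of sample ids.
#' @export
stratified_split <- function(samples, train_frac = 65 / 91, n_bins = 5L,
                             seed = 1L, unit = c("sample", "individual")) {
  unit <- match.arg(unit)
  if (!is.finite(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must lie strictly between 0 and 1")
  }
  set.seed(seed)
  if (unit == "individual") {
    first_age <- vapply(split(samples$age_years, samples$individual_id), min, 0)
    units <- data.frame(id = names(first_age), age = first_age)
  } else {
    units <- data.frame(id = samples$sample_id, age = samples$age_years)
  }
  n <- nrow(units)
  brk <- unique(stats::quantile(units$age, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(units$age, breaks = brk, include.lowest = TRUE)
  counts <- table(bin)
  share <- train_frac * as.numeric(counts)
  n_train_bin <- floor(share)
  want <- round(train_frac * n)
  extra <- want - sum(n_train_bin)
  if (extra > 0) {
    ord <- order(share - n_train_bin, decreasing = TRUE)
    n_train_bin[ord[seq_len(extra)]] <- n_train_bin[ord[seq_len(extra)]] + 1
  }
  train_units <- character(0)
  for (b in seq_along(levels(bin))) {
    ids <- units$id[bin == levels(bin)[b]]
    n_tr <- min(n_train_bin[b], length(ids))
    if (n_tr > 0) train_units <- c(train_units, sample(ids, n_tr))
  }
  if (unit == "individual") {
    tr <- samples$sample_id[samples$individual_id %in% train_units]
    te <- setdiff(samples$sample_id, tr)
  } else {
    tr <- train_units
    te <- setdiff(units$id, tr)
  }
  list(train = tr, test = te)
}

#' Select age-correlated CpG sites
#'
#' Pearson-correlation feature pre-selection: sites whose correlation with
#' chronological age exceeds the threshold strictly (`|r| > threshold` by
#' default; `r > threshold` in signed mode) are returned in deterministic
#' order (descending `|r|`, then site key). Zero-variance sites are skipped
#' with a warning (their correlation is undefined).
#'
#' @param x Numeric matrix, sites x samples (normalised values).
#' @param ages Chronological ages, one per column of `x`.
#' @param threshold Correlation cutoff (strict inequality).
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return Data.frame with `site` and `r`.
#' @export
select_features <- function(x, ages, threshold = 0.5,
                            mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), length(ages) == ncol(x))
  if (ncol(x) < 3L) stop("at least 3 samples are required")
  if (anyNA(x)) stop("matrix must be complete")
  sds <- apply(x, 1L, stats::sd)
  zero <- sds == 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance site(s) skipped (correlation undefined)",
                    sum(zero)))
  }
  r <- rep(NA_real_, nrow(x))
  r[!zero] <- as.vector(stats::cor(t(x[!zero, , drop = FALSE]), ages))
  sel <- if (mode == "absolute") !zero & abs(r) > threshold else !zero & r > threshold
  keys <- rownames(x)
  out <- data.frame(site = keys[sel], r = r[sel], stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r), out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

standardize_cols <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  scl <- sqrt(colMeans(Xc^2))  # population SD, so sum(x^2)/n == 1
  keep <- scl > 0
  Xs <- sweep(Xc[, keep, drop = FALSE], 2L, scl[keep], "/")
  list(Xs = Xs, center = ctr, scale = scl, keep = keep)
}

make_lambda_seq <- function(lambda_max, lambda, nlambda, lambda_min_ratio) {
  lambda_max <- max(lambda_max, .Machine$double.eps)
  if (identical(lambda, "cv")) {
    return(exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                   length.out = nlambda)))
  }
  lambda <- as.numeric(lambda)
  if (lambda >= lambda_max) return(c(lambda_max, lambda)[c(lambda > lambda_max, TRUE)])
  lo <- max(lambda, lambda_max * 1e-4)
  path <- exp(seq(log(lambda_max), log(lo), length.out = 25L))
  if (lambda < lo) path <- c(path, lambda)
  path[length(path)] <- lambda
  path
}

assign_folds <- function(n, n_folds, groups = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(groups)) {
    return(sample(rep(seq_len(n_folds), length.out = n)))
  }
  g <- unique(groups)
  gf <- sample(rep(seq_len(n_folds), length.out = length(g)))
  gf[match(groups, g)]
}

#' Fit an elastic-net age model
#'
#' Minimises `(1/2n) * sum((y - b0 - X b)^2) + lambda * (alpha * ||b||_1 +
#' (1 - alpha)/2 * ||b||_2^2)` by cyclic coordinate descent with
#' soft-thresholding (compiled), on internally standardised features;
#' coefficients are returned on the caller's scale. With `lambda = "cv"` a
#' 100-point log-spaced path from `lambda_max` down to
#' `lambda_min_ratio * lambda_max` is scored by n-fold cross-validation and
#' the MSE-minimising lambda is kept, along with the CV curve and the
#' held-out predictions at that lambda. `lambda_max` is the smallest penalty
#' with an all-zero lasso solution, `max|x' y| / (n * max(alpha, 0.001))`
#' (the denominator floor makes the ridge end of the grid finite).
#'
#' @param X Numeric matrix, samples x features (complete, finite).
#' @param y Response (ages, years).
#' @param alpha Elastic-net mixing in \[0, 1\] (0 = ridge, 1 = lasso).
#' @param lambda Penalty strength, or `"cv"` to tune it.
#' @param n_folds Folds for the internal cross-validation.
#' @param seed Seed for the fold assignment.
#' @param foldid Optional explicit fold id per row (overrides `seed`).
#' @param groups Optional grouping labels (e.g. individual ids); internal CV
#'   folds then keep a group's rows together.
#' @param nlambda,lambda_min_ratio Path resolution for `lambda = "cv"`.
#' @param tol Convergence tolerance on the maximum coefficient change
#'   (standardised scale).
#' @param max_iter Maximum coordinate-descent sweeps per lambda.
#' @return An object of class `enet_fit`: `coefficients` (named, caller's
#'   scale), `intercept`, `alpha`, `lambda`, and for CV fits `cv_curve`
#'   (lambda, mse), `cv_pred`, `cv_r2`.
#' @export
fit_elastic_net <- function(X, y, alpha, lambda = "cv", n_folds = 10L,
                            seed = 1L, foldid = NULL, groups = NULL,
                            nlambda = 100L, lambda_min_ratio = 1e-3,
                            tol = 1e-7, max_iter = 1e5L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite inputs")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  std <- standardize_cols(X)
  y_center <- mean(y)
  yc <- y - y_center
  p_kept <- ncol(std$Xs)
  if (p_kept == 0L) {
    fit <- list(coefficients = stats::setNames(rep(0, ncol(X)), colnames(X)),
                intercept = y_center, alpha = alpha,
                lambda = if (identical(lambda, "cv")) NA_real_ else lambda,
                cv_curve = NULL, cv_pred = NULL, cv_r2 = NA_real_,
                beta_std = numeric(0), x_center = std$center,
                x_scale = std$scale, keep = std$keep, y_center = y_center)
    class(fit) <- "enet_fit"
    return(fit)
  }
  lambda_max <- max(abs(crossprod(std$Xs, yc))) / (n * max(alpha, 0.001))
  lam_seq <- make_lambda_seq(lambda_max, lambda, nlambda, lambda_min_ratio)

  cv_curve <- NULL; cv_pred <- NULL; cv_r2 <- NA_real_
  if (identical(lambda, "cv")) {
    if (n < n_folds) stop("need at least n_folds rows for lambda CV")
    if (is.null(foldid)) foldid <- assign_folds(n, n_folds, groups, seed)
    pred <- matrix(NA_real_, n, length(lam_seq))
    for (f in sort(unique(foldid))) {
      tr <- foldid != f
      std_f <- standardize_cols(X[tr, , drop = FALSE])
      if (ncol(std_f$Xs) == 0L) {
        pred[!tr, ] <- mean(y[tr])
        next
      }
      yc_f <- y[tr] - mean(y[tr])
      path <- enet_path_cpp(std_f$Xs, yc_f, alpha, lam_seq, tol, as.integer(max_iter))
      Xte <- X[!tr, std_f$keep, drop = FALSE]
      Xte <- sweep(sweep(Xte, 2L, std_f$center[std_f$keep]), 2L,
                   std_f$scale[std_f$keep], "/")
      pred[!tr, ] <- mean(y[tr]) + Xte %*% path$beta
    }
    mse <- colMeans((pred - y)^2)
    best <- which.min(mse)
    cv_curve <- data.frame(lambda = lam_seq, mse = mse)
    cv_pred <- pred[, best]
    cv_r2 <- if (stats::sd(cv_pred) > 0) stats::cor(cv_pred, y)^2 else 0
    chosen <- lam_seq[best]
    lam_fit <- lam_seq[seq_len(best)]
  } else {
    chosen <- as.numeric(lambda)
    lam_fit <- lam_seq
  }

  path <- enet_path_cpp(std$Xs, yc, alpha, lam_fit, tol, as.integer(max_iter))
  beta_std <- path$beta[, length(lam_fit)]
  beta <- rep(0, ncol(X))
  beta[std$keep] <- beta_std / std$scale[std$keep]
  names(beta) <- colnames(X)
  intercept <- y_center - sum(beta[std$keep] * std$center[std$keep])

  fit <- list(coefficients = beta, intercept = intercept, alpha = alpha,
              lambda = chosen, cv_curve = cv_curve, cv_pred = cv_pred,
              cv_r2 = cv_r2, beta_std = beta_std, x_center = std$center,
              x_scale = std$scale, keep = std$keep, y_center = y_center,
              sweeps = path$sweeps)
  class(fit) <- "enet_fit"
  fit
}

#' @export
predict.enet_fit <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  drop(object$intercept + newx %*% object$coefficients)
}

#' @export
print.enet_fit <- function(x, ...) {
  cat(sprintf("enet_fit: alpha = %.3g, lambda = %.4g, %d/%d non-zero coefficients\n",
              x$alpha, x$lambda, sum(x$coefficients != 0), length(x$coefficients)))
  invisible(x)
}

#' Karush-Kuhn-Tucker residual of an elastic-net fit
#'
#' Maximum violation of the stationarity conditions on the standardised
#' scale: for an active coefficient,
#' `|x_j' r / n - lambda (1 - alpha) b_j - lambda alpha sign(b_j)|`; for an
#' inactive one, the excess of `|x_j' r / n|` over `lambda * alpha`. A
#' converged fit has a residual at the order of the convergence tolerance.
#'
#' @param fit An `enet_fit`.
#' @param X,y The data the fit was computed on.
#' @return The maximum KKT violation (scalar).
#' @export
kkt_residual <- function(fit, X, y) {
  X <- as.matrix(X)
  keep <- fit$keep
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, fit$x_center[keep]),
              2L, fit$x_scale[keep], "/")
  yc <- y - fit$y_center
  b <- fit$beta_std
  r <- yc - Xs %*% b
  g <- as.vector(crossprod(Xs, r)) / nrow(X)
  lam <- fit$lambda; alpha <- fit$alpha
  active <- b != 0
  v_active <- if (any(active)) {
    max(abs(g[active] - lam * (1 - alpha) * b[active] - lam * alpha * sign(b[active])))
  } else 0
  v_inactive <- if (any(!active)) max(0, max(abs(g[!active])) - lam * alpha) else 0
  max(v_active, v_inactive)
}

#' Grid search over the elastic-net mixing parameter
#'
#' For each alpha on the grid, lambda is tuned by internal cross-validation
#' and the cross-validated R-squared (squared Pearson correlation between
#' held-out predictions and age) is recorded; the alpha with the highest CV
#' R-squared wins, ties broken toward the larger alpha (the sparser model).
#' The same fold assignment is reused across alphas so the comparison is
#' paired.
#'
#' @inheritParams fit_elastic_net
#' @param alpha_grid Candidate alphas (default 0 to 1 in steps of 0.01).
#' @return List: `alpha`, `lambda`, `cv_r2`, and `table` with one row per
#'   alpha.
#' @export
grid_search_alpha <- function(X, y, alpha_grid = seq(0, 1, by = 0.01),
                              groups = NULL, seed = 1L, n_folds = 10L) {
  foldid <- assign_folds(nrow(as.matrix(X)), n_folds, groups, seed)
  tab <- data.frame(alpha = alpha_grid, lambda = NA_real_, cv_r2 = NA_real_)
  best <- NULL
  for (i in seq_along(alpha_grid)) {
    fit <- fit_elastic_net(X, y, alpha = alpha_grid[i], lambda = "cv",
                           foldid = foldid)
    tab$lambda[i] <- fit$lambda
    tab$cv_r2[i] <- fit$cv_r2
    if (is.null(best) || fit$cv_r2 >= best$cv_r2) {  # >= : ties go to larger alpha
      best <- list(alpha = alpha_grid[i], lambda = fit$lambda, cv_r2 = fit$cv_r2)
    }
  }
  c(best, list(table = tab))
}

#' Support-vector regression comparator (RBF kernel)
#'
#' Epsilon-SVR with a radial basis function kernel, the standard comparator
#' for penalised-regression clocks. A thin wrapper over [e1071::svm()].
#'
#' @param X Numeric matrix, samples x features.
#' @param y Ages.
#' @param cost,gamma,epsilon SVR hyperparameters (defaults as in e1071:
#'   `gamma = 1/ncol(X)`).
#' @return Fitted `svm` model (use `predict()`).
#' @export
fit_svr_rbf <- function(X, y, cost = 1, gamma = NULL, epsilon = 0.1) {
  X <- as.matrix(X)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
             cost = cost, gamma = gamma, epsilon = epsilon)
}

#' Train a full methylation clock
#'
#' Runs the modelling pipeline on a complete ratio matrix: per-sample
#' rank-normalisation over the candidate universe, correlation-based feature
#' selection, then an elastic-net fit (with alpha tuned on a grid when
#' `alpha = "grid"`, and lambda by internal CV). The returned model carries
#' everything needed to predict new samples: the candidate universe, the
#' training-set site means (for imputing sparsely missing sites at
#' prediction time), selected sites and coefficients.
#'
#' @param ratios Complete methylation-ratio matrix, sites x samples
#'   (post-filtering, post-imputation).
#' @param samples Sample records aligned with the columns.
#' @param alpha `"grid"` or a fixed value in \[0, 1\].
#' @param alpha_grid Grid used when `alpha = "grid"`.
#' @param lambda `"cv"` or a fixed penalty.
#' @param threshold Feature-selection cutoff on `|r|`.
#' @param selection_mode `"absolute"` or `"signed"` (see [select_features()]).
#' @param seed Seed for CV fold assignment.
#' @return An object of class `ClockModel`.
#' @export
train_clock <- function(ratios, samples, alpha = "grid",
                        alpha_grid = seq(0, 1, by = 0.01), lambda = "cv",
                        threshold = 0.5,
                        selection_mode = c("absolute", "signed"), seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  stopifnot(is.matrix(ratios), ncol(ratios) == nrow(samples))
  ages <- samples$age_years
  norm <- rank_normal(ratios)
  sel <- select_features(norm, ages, threshold = threshold, mode = selection_mode)
  if (nrow(sel) == 0L) stop("no site passed the correlation threshold")
  Xtr <- t(norm[sel$site, , drop = FALSE])
  if (identical(alpha, "grid")) {
    gs <- grid_search_alpha(Xtr, ages, alpha_grid = alpha_grid,
                            groups = samples$individual_id, seed = seed)
    alpha_use <- gs$alpha
  } else {
    alpha_use <- as.numeric(alpha)
    gs <- NULL
  }
  fit <- fit_elastic_net(Xtr, ages, alpha = alpha_use, lambda = lambda,
                         groups = samples$individual_id, seed = seed)
  model <- list(candidate_universe = rownames(ratios),
                site_means = rowMeans(ratios),
                selected_sites = sel$site,
                selection_r = stats::setNames(sel$r, sel$site),
                selection_threshold = threshold,
                selection_mode = selection_mode,
                coefficients = fit$coefficients,
                intercept = fit$intercept,
                alpha = fit$alpha, lambda = fit$lambda,
                alpha_search = gs$table, fit = fit)
  class(model) <- "ClockModel"
  model
}

#' @export
print.ClockModel <- function(x, ...) {
  cat(sprintf("ClockModel: %d clock CpGs (of %d candidates), alpha = %.3g, lambda = %.4g\n",
              length(x$selected_sites), length(x$candidate_universe),
              x$alpha, x$lambda))
  cat(sprintf("  non-zero coefficients: %d; intercept %.2f years\n",
              sum(x$coefficients != 0), x$intercept))
  invisible(x)
}

#' Predict DNA-methylation age for new samples
#'
#' New samples are rank-normalised over the model's candidate-site universe
#' (exactly as at training time; per-sample, so no training state leaks),
#' clock sites extracted, and the affine model applied. Up to 5% of the
#' candidate universe may be missing per sample, filled with the stored
#' training-set site means; beyond that an error advises re-sequencing.
#' Predictions are returned as-is (negative ages are possible and reported).
#'
#' @param model A `ClockModel`.
#' @param ratios Named numeric vector (one sample) or matrix sites x samples
#'   of raw methylation ratios; rownames must use the model's site keys.
#' @return Numeric vector of DNAm ages (years), one per sample.
#' @export
predict_age <- function(model, ratios) {
  stopifnot(inherits(model, "ClockModel"))
  if (is.null(dim(ratios))) ratios <- matrix(ratios, ncol = 1,
                                             dimnames = list(names(ratios), "sample"))
  uni <- model$candidate_universe
  m <- matrix(NA_real_, length(uni), ncol(ratios),
              dimnames = list(uni, colnames(ratios)))
  hit <- intersect(rownames(ratios), uni)
  m[hit, ] <- ratios[hit, , drop = FALSE]
  frac_missing <- colMeans(is.na(m))
  if (any(frac_missing > 0.05)) {
    stop(sprintf("sample(s) missing > 5%% of the candidate universe (worst: %.1f%%); re-sequence or relax the universe",
                 100 * max(frac_missing)))
  }
  for (j in seq_len(ncol(m))) {
    na <- is.na(m[, j])
    m[na, j] <- model$site_means[na]
  }
  norm <- rank_normal(m)
  xs <- t(norm[model$selected_sites, , drop = FALSE])
  drop(model$intercept + xs %*% model$coefficients)
}

#' Leave-one-individual-out cross-validation of the clock pipeline
#'
#' One fold per individual: all of that individual's samples are held out,
#' the pipeline is refit on the remaining samples, and the held-out samples
#' are predicted. With `selection_mode = "paper"` feature selection is done
#' once on all samples before the folds (pre-selection followed by
#' regression); `"nested"` re-selects within each fold, quantifying the
#' leakage of pre-selection. Normalisation is per-sample and therefore
#' identical inside and outside any fold.
#'
#' @param ratios Complete ratio matrix, sites x samples.
#' @param samples Sample records aligned with the columns.
#' @param alpha Elastic-net mixing used in every fold.
#' @param lambda `"cv"` (tuned per fold) or fixed.
#' @param threshold Feature-selection cutoff.
#' @param selection_mode `"paper"` or `"nested"`.
#' @param seed Seed for the per-fold internal CV.
#' @return List of class `loiocv_result`: `predictions` (one row per sample:
#'   `sample_id`, `individual_id`, `age_years`, `dnam_age`, `fold`),
#'   `metrics` (see [compute_metrics()]), and `folds` (per fold, the held-out
#'   individual and the training individuals, for purity audits).
#' @export
loiocv <- function(ratios, samples, alpha, lambda = "cv", threshold = 0.5,
                   selection_mode = c("paper", "nested"), seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  stopifnot(is.matrix(ratios), ncol(ratios) == nrow(samples))
  inds <- unique(samples$individual_id)
  if (length(inds) < 3L) stop("at least 3 distinct individuals are required")
  if (any(table(samples$individual_id) == nrow(samples))) {
    stop("one individual owns every sample; cross-validation is impossible")
  }
  norm <- rank_normal(ratios)
  ages <- samples$age_years
  sel_all <- if (selection_mode == "paper") {
    select_features(norm, ages, threshold = threshold)
  } else NULL

  pred <- rep(NA_real_, nrow(samples))
  fold_of <- match(samples$individual_id, inds)
  folds <- vector("list", length(inds))
  for (f in seq_along(inds)) {
    te <- fold_of == f
    tr <- !te
    sel <- if (selection_mode == "paper") sel_all else {
      select_features(norm[, tr, drop = FALSE], ages[tr], threshold = threshold)
    }
    if (nrow(sel) == 0L) {
      pred[te] <- mean(ages[tr])  # no informative site in this fold
    } else {
      Xtr <- t(norm[sel$site, tr, drop = FALSE])
      fit <- fit_elastic_net(Xtr, ages[tr], alpha = alpha, lambda = lambda,
                             groups = samples$individual_id[tr], seed = seed)
      pred[te] <- predict(fit, t(norm[sel$site, te, drop = FALSE]))
    }
    folds[[f]] <- list(held_out = inds[f],
                       train_individuals = unique(samples$individual_id[tr]))
  }
  predictions <- data.frame(sample_id = samples$sample_id,
                            individual_id = samples$individual_id,
                            sex = if ("sex" %in% names(samples)) samples$sex else NA,
                            age_years = ages, dnam_age = pred,
                            fold = samples$individual_id,
                            stringsAsFactors = FALSE)
  structure(list(predictions = predictions,
                 metrics = compute_metrics(predictions),
                 folds = folds,
                 selected_sites = if (is.null(sel_all)) NULL else sel_all),
            class = "loiocv_result")
}

#' @export
print.loiocv_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("LOIOCV over %d folds / %d samples: MAE %.2f y, r %.3f, R2 %.3f\n",
              length(x$folds), nrow(x$predictions), m$mae, m$pearson_r, m$r2))
  invisible(x)
}
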