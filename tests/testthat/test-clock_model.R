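test_that("stratified splitting reproduces the 65/26 design and respects bins", {
  samples <- tiny_metadata(sprintf("s%02d", 1:91), age = seq(0, 56, length.out = 91))
  sp <- stratified_split(samples, train_frac = 65 / 91, n_bins = 5, seed = 2)
  expect_equal(length(sp$train), 65L)
  expect_equal(length(sp$test), 26L)
  expect_setequal(c(sp$train, sp$test), samples$sample_id)
  expect_error(stratified_split(samples, train_frac = 1.2), "train_frac")

  # per-bin train proportion concentrates on train_frac over seeded splits
  set.seed(3)
  props <- replicate(300, {
    s <- stratified_split(samples, train_frac = 0.7, n_bins = 5,
                          seed = sample.int(1e6, 1))
    length(s$train) / 91
  })
  expect_lt(abs(mean(props) - 0.7), 0.01)
})

test_that("individual-unit splits keep an animal's repeats on one side", {
  samples <- tiny_metadata(sprintf("s%02d", 1:40),
                           ind = rep(sprintf("i%02d", 1:10), each = 4),
                           age = rep(seq(2, 50, length.out = 10), each = 4) + 0:3)
  sp <- stratified_split(samples, train_frac = 0.7, n_bins = 3, seed = 5,
                         unit = "individual")
  side <- ifelse(samples$sample_id %in% sp$train, "train", "test")
  expect_true(all(tapply(side, samples$individual_id,
                         function(s) length(unique(s))) == 1L))
})

test_that("feature selection is strict at the threshold and ordered by |r|", {
  set.seed(11)
  n <- 40
  ages <- runif(n, 0, 50)
  a <- scale(ages)[, 1]
  z <- residuals(lm(rnorm(n) ~ ages)); z <- z / sd(z)  # orthogonal to ages
  x_half <- 0.5 * a + sqrt(1 - 0.25) * z          # sample r exactly 0.5
  x <- rbind(site_a = ages, x_half = x_half, neg = -0.8 * a + 0.6 * z,
             flat = rep(1, n))
  rownames(x) <- c("chr1:10", "chr1:20", "chr1:30", "chr1:40")
  r20 <- abs(cor(x["chr1:20", ], ages))
  expect_equal(r20, 0.5, tolerance = 1e-12)
  # strictness at the boundary: a site exactly at the threshold is excluded
  expect_warning(sel <- select_features(x, ages, threshold = r20),
                 "zero-variance")
  expect_true("chr1:10" %in% sel$site)       # r = 1
  expect_false("chr1:20" %in% sel$site)      # |r| equals the cutoff exactly
  expect_true("chr1:30" %in% sel$site)       # |r| = 0.8 under absolute mode
  expect_equal(sel$site[1], "chr1:10")       # descending |r|

  sgn <- suppressWarnings(select_features(x, ages, threshold = 0.5, mode = "signed"))
  expect_false("chr1:30" %in% sgn$site)      # negative r not selected in signed mode
})

test_that("elastic net matches ridge and OLS closed forms and the lasso null", {
  set.seed(42)
  n <- 50; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% rnorm(p)) + rnorm(n)
  colnames(X) <- paste0("f", 1:p)

  lam <- 0.7
  f_ridge <- fit_elastic_net(X, y, alpha = 0, lambda = lam)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  scl <- sqrt(colMeans(Xc^2))
  Xs <- sweep(Xc, 2, scl, "/")
  yc <- y - mean(y)
  b_oracle <- solve(crossprod(Xs) / n + lam * diag(p), crossprod(Xs, yc) / n)
  expect_lt(max(abs(f_ridge$coefficients - drop(b_oracle) / scl)), 1e-6)

  f_ols <- fit_elastic_net(X, y, alpha = 0.5, lambda = 0)
  b_lm <- coef(lm(y ~ X))
  expect_lt(max(abs(f_ols$coefficients - b_lm[-1])), 1e-6)
  expect_lt(abs(f_ols$intercept - b_lm[1]), 1e-6)

  x1 <- X[, 1, drop = FALSE]
  x1s <- (x1 - mean(x1)) / sqrt(mean((x1 - mean(x1))^2))
  lmax <- abs(sum(x1s * yc)) / n
  f_null <- fit_elastic_net(x1, y, alpha = 1, lambda = lmax)
  expect_identical(unname(f_null$coefficients), 0)
  expect_error(fit_elastic_net(X * NA, y, alpha = 0.5, lambda = 1), "non-finite")
})

test_that("elastic-net fits satisfy KKT conditions and beat the reference solver's objective", {
  skip_if_not_installed("glmnet")
  set.seed(7)
  n <- 60; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:4] %*% c(3, -2, 1.5, 1)) + rnorm(n)
  # glmnet standardises the response internally, which reweights the ridge
  # part of the penalty relative to the written objective; comparing on a
  # unit-variance response removes that discrepancy
  ys <- y / sqrt(mean((y - mean(y))^2))
  for (alpha in c(0.2, 0.5, 1)) {
    f_raw <- fit_elastic_net(X, y, alpha = alpha, lambda = 0.15)
    expect_lt(kkt_residual(f_raw, X, y), 1e-6)

    f <- fit_elastic_net(X, ys, alpha = alpha, lambda = 0.15)
    g <- glmnet::glmnet(X, ys, alpha = alpha, standardize = TRUE,
                        lambda = exp(seq(log(2), log(0.15), length.out = 60)),
                        thresh = 1e-14)
    bg <- as.numeric(coef(g, s = 0.15))
    expect_lt(max(abs(c(f$intercept, f$coefficients) - bg)), 1e-6)
    obj <- function(b0, b) {
      scl <- sqrt(colMeans(scale(X, scale = FALSE)^2))
      bs <- b * scl
      mean((ys - b0 - X %*% b)^2) / 2 +
        0.15 * (alpha * sum(abs(bs)) + (1 - alpha) / 2 * sum(bs^2))
    }
    expect_lte(obj(f$intercept, f$coefficients), obj(bg[1], bg[-1]) + 1e-10)
  }
})

test_that("lambda CV tracks the MSE-minimising penalty and the path has 100 points", {
  set.seed(13)
  n <- 60; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:3] %*% c(4, 3, -2)) + rnorm(n, 0, 0.5)
  f <- fit_elastic_net(X, y, alpha = 0.5, lambda = "cv", seed = 2)
  expect_equal(nrow(f$cv_curve), 100L)
  expect_equal(f$lambda, f$cv_curve$lambda[which.min(f$cv_curve$mse)])
  expect_gt(f$cv_r2, 0.9)
  expect_equal(length(f$cv_pred), n)
})

test_that("the alpha grid evaluates every candidate, recovers noiseless signals, and breaks ties sparser", {
  set.seed(17)
  n <- 40
  X <- matrix(rnorm(n * 6), n, 6)
  y <- drop(X[, 1:3] %*% c(2, -1, 3))   # noiseless
  gs <- grid_search_alpha(X, y, alpha_grid = seq(0, 1, by = 0.01), seed = 4)
  expect_equal(nrow(gs$table), 101L)
  expect_gte(gs$cv_r2, 0.99)

  y_flat <- rep(5, n)                    # every alpha ties at R^2 = 0
  gs_tie <- grid_search_alpha(X, y_flat, alpha_grid = c(0.2, 0.5, 0.8), seed = 4)
  expect_equal(gs_tie$alpha, 0.8)
})

test_that("the SVR comparator interpolates smooth noiseless data and flattens to the mean", {
  set.seed(19)
  X <- matrix(runif(60, -2, 2), ncol = 1)
  y <- sin(X[, 1])
  m <- fit_svr_rbf(X, y, cost = 100, gamma = 1, epsilon = 0.05)
  expect_lt(mean((predict(m, X) - y)^2), 0.05^2)

  m_flat <- fit_svr_rbf(X, y, cost = 10, gamma = 1e-8, epsilon = 0.01)
  expect_lt(max(abs(predict(m_flat, X) - mean(y))), 0.25)
})

test_that("LOIOCV gives one fold per individual, predicts each sample once, and never leaks", {
  spec <- cohort_spec(n_individuals = 10, n_sites = 400, p_age = 0.25,
                      sigma_site = 0.1, coverage_mean = 60, seed = 23)
  co <- simulate_cohort(spec)
  ratios <- impute_knn(get_ratios(filter_sites(co$dataset)$dataset))
  cv <- loiocv(ratios, co$samples, alpha = 0.5, lambda = "cv", seed = 1)
  expect_equal(length(cv$folds), 10L)
  expect_setequal(cv$predictions$sample_id, co$samples$sample_id)
  expect_false(anyNA(cv$predictions$dnam_age))
  for (f in cv$folds) {
    expect_false(f$held_out %in% f$train_individuals)
  }
  multi <- names(which(table(co$samples$individual_id) >= 2))[1]
  f_multi <- cv$folds[[match(multi, vapply(cv$folds, `[[`, "", "held_out"))]]
  expect_false(multi %in% f_multi$train_individuals)

  expect_error(loiocv(ratios, transform(co$samples, individual_id = "one"),
                      alpha = 0.5), "3 distinct individuals")
})

test_that("LOIOCV recovers a noiseless linear clock nearly perfectly", {
  set.seed(29)
  n_ind <- 12
  samples <- tiny_metadata(sprintf("s%02d", 1:36),
                           ind = rep(sprintf("i%d", 1:n_ind), each = 3),
                           age = runif(36, 0, 50))
  ages <- samples$age_years
  p <- 60
  # noiseless logit-linear sites with mixed slopes and baselines, so the
  # within-sample rank order itself changes smoothly with age
  b0 <- runif(p, -2.5, 1.5)
  b1 <- runif(p, 0.02, 0.09) * rep(c(1, -1), length.out = p)
  ratios <- vapply(seq_along(ages),
                   function(i) plogis(b0 + b1 * ages[i]), numeric(p))
  rownames(ratios) <- sprintf("chr1:%d", seq_len(p) * 100)
  colnames(ratios) <- samples$sample_id
  cv <- loiocv(ratios, samples, alpha = 0.5, lambda = "cv", threshold = 0.5,
               seed = 1)
  expect_gte(cv$metrics$pearson_r, 0.99)
})

test_that("prediction is affine, order-invariant, and consistent with training fits", {
  spec <- cohort_spec(n_individuals = 10, n_sites = 300, p_age = 0.3,
                      sigma_site = 0.1, coverage_mean = 60,
                      missing_prob = 0, seed = 37)
  co <- simulate_cohort(spec)
  ratios <- impute_knn(get_ratios(filter_sites(co$dataset)$dataset))
  model <- train_clock(ratios, co$samples, alpha = 0.5, seed = 1)

  pred <- predict_age(model, ratios)
  norm <- rank_normal(ratios)
  fitted_manual <- drop(model$intercept +
                          t(norm[model$selected_sites, ]) %*% model$coefficients)
  expect_equal(unname(pred), unname(fitted_manual), tolerance = 1e-10)

  shuffle <- sample(nrow(ratios))
  pred_shuffled <- predict_age(model, ratios[shuffle, ])
  expect_equal(pred, pred_shuffled)

  zero_model <- model
  zero_model$coefficients[] <- 0
  expect_equal(unname(predict_age(zero_model, ratios[, 1])),
               zero_model$intercept)

  too_sparse <- ratios[seq_len(floor(nrow(ratios) * 0.9)), 1, drop = FALSE]
  expect_error(predict_age(model, too_sparse), "5%")
})

test_that("nested selection does not outperform pooled pre-selection on average", {
  r2 <- matrix(NA_real_, 3, 2)
  for (s in 1:3) {
    spec <- cohort_spec(n_individuals = 9, n_sites = 300, p_age = 0.1,
                        sigma_site = 0.5, coverage_mean = 20, seed = 100 + s)
    co <- simulate_cohort(spec)
    ratios <- impute_knn(get_ratios(filter_sites(co$dataset)$dataset))
    cv_p <- loiocv(ratios, co$samples, alpha = 0.5, threshold = 0.4,
                   selection_mode = "paper", seed = 1)
    cv_n <- loiocv(ratios, co$samples, alpha = 0.5, threshold = 0.4,
                   selection_mode = "nested", seed = 1)
    r2[s, ] <- c(cv_p$metrics$r2, cv_n$metrics$r2)
  }
  # leakage direction: pooled pre-selection should look at least as good
  expect_gte(mean(r2[, 1]), mean(r2[, 2]) - 0.05)
})
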