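test_that("relative error reproduces the lifespan-normalised headline arithmetic", {
  expect_equal(round(relative_error(4.82, 79.6), 2), 6.06)
  # scales inversely with the lifespan used
  expect_equal(relative_error(4.82, 79.6 * 2) * 2, relative_error(4.82, 79.6))
})

test_that("metrics are exact on perfect predictions and match a formula oracle", {
  pred <- data.frame(age_years = c(1, 5, 20, 43), dnam_age = c(1, 5, 20, 43))
  m <- compute_metrics(pred)
  expect_equal(m$mae, 0)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$r2, 1)

  set.seed(41)
  for (i in 1:5) {
    y <- runif(200, 0, 60)
    p <- y + rnorm(200, 0, 5)
    mm <- compute_metrics(data.frame(age_years = y, dnam_age = p),
                          max_lifespan = 79.6)
    expect_equal(mm$mae, mean(abs(p - y)), tolerance = 1e-12)
    r_oracle <- sum((y - mean(y)) * (p - mean(p))) /
      sqrt(sum((y - mean(y))^2) * sum((p - mean(p))^2))
    expect_equal(mm$pearson_r, r_oracle, tolerance = 1e-12)
    expect_equal(mm$relative_error_pct, 100 * mm$mae / 79.6, tolerance = 1e-12)
  }
  expect_error(compute_metrics(data.frame(age_years = c(1, 1), dnam_age = c(2, 3))),
               "zero variance")
})

test_that("delta-age residuals are OLS residuals with mean zero", {
  pred <- data.frame(age_years = c(1, 5, 20, 43), dnam_age = c(1, 5, 20, 43))
  expect_equal(unname(delta_age_residuals(pred)), rep(0, 4))

  set.seed(43)
  y <- runif(50, 0, 60)
  p <- 3 + 0.9 * y + rnorm(50, 0, 4)
  d <- delta_age_residuals(data.frame(age_years = y, dnam_age = p))
  expect_lt(abs(mean(d)), 1e-10)
  # normal-equations oracle
  A <- cbind(1, y)
  beta <- solve(crossprod(A), crossprod(A, p))
  expect_equal(unname(d), unname(p - drop(A %*% beta)), tolerance = 1e-10)
  expect_error(delta_age_residuals(data.frame(age_years = rep(2, 5),
                                              dnam_age = 1:5)), "constant")
})

test_that("age classes partition the lifespan with half-open boundaries", {
  expect_equal(as.character(assign_age_class(0.5)), "calf")
  expect_equal(as.character(assign_age_class(c(1, 5, 20, 50))),
               c("juvenile", "subadult", "adult", "senior"))
  expect_equal(as.character(assign_age_class(55)), "senior")
  expect_error(assign_age_class(-1), "non-negative")

  # first-sampling ages of the published longitudinal table, hand-enumerated
  tab <- elephant_longitudinal_ages()
  cls <- assign_age_class(tab$age_first)
  hand <- c(calf = 1L, juvenile = 0L, subadult = 9L, adult = 7L, senior = 0L)
  expect_equal(as.integer(table(cls)), unname(hand))
})

test_that("class comparisons: null case, power sanity, and the sums-of-squares oracle", {
  pred0 <- data.frame(age_years = c(rep(0.5, 5), rep(3, 5)),
                      dnam_age = rep(c(1, 2, 3, 4, 5), 2))
  r0 <- compare_age_classes(pred0)
  expect_lt(r0$anova$f, 1e-10)
  expect_gt(min(r0$pairwise, na.rm = TRUE), 0.99)
  expect_equal(unname(r0$letters[1]), unname(r0$letters[2]))

  set.seed(47)
  pred1 <- data.frame(age_years = c(runif(20, 0, 0.9), runif(20, 30, 45)),
                      dnam_age = c(rnorm(20, 0, 1), rnorm(20, 100, 1)))
  r1 <- compare_age_classes(pred1)
  expect_lt(r1$anova$p, 1e-10)

  set.seed(48)
  ages <- c(runif(8, 0, 1), runif(8, 2, 4), runif(8, 6, 19), runif(8, 21, 49),
            runif(8, 50, 56))
  pred2 <- data.frame(age_years = ages, dnam_age = ages + rnorm(40, 0, 3))
  r2 <- compare_age_classes(pred2)
  cls <- assign_age_class(ages)
  grand <- mean(pred2$dnam_age)
  ssb <- sum(tapply(pred2$dnam_age, cls, function(g) length(g) * (mean(g) - grand)^2))
  ssw <- sum(tapply(pred2$dnam_age, cls, function(g) sum((g - mean(g))^2)))
  f_oracle <- (ssb / 4) / (ssw / 35)
  expect_equal(r2$anova$f, f_oracle, tolerance = 1e-10)

  # with exactly two groups the ANOVA F is the squared pooled t statistic
  two <- data.frame(age_years = c(runif(10, 0, 0.9), runif(10, 30, 45)),
                    dnam_age = rnorm(20, rep(c(5, 30), each = 10), 2))
  rt <- compare_age_classes(two)
  tt <- t.test(dnam_age ~ assign_age_class(age_years), data = two,
               var.equal = TRUE)
  expect_equal(rt$anova$f, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("PCA: rank-1 structure, orthogonal scores, and age alignment of PC1", {
  s1 <- seq(0.1, 0.9, length.out = 12)
  x <- rbind(a = s1, b = 2 * s1 + 1)
  p <- pca_project(x, scale = TRUE)
  expect_equal(p$var_frac[1], 1, tolerance = 1e-10)

  set.seed(51)
  y <- matrix(rnorm(30 * 10), 10, 30)
  rownames(y) <- paste0("s", 1:10)
  pp <- pca_project(y)
  g <- crossprod(pp$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)

  spec <- cohort_spec(n_individuals = 15, n_sites = 200, p_age = 0.5,
                      sigma_site = 0.2, coverage_mean = 60, seed = 53)
  co <- simulate_cohort(spec)
  ratios <- impute_knn(get_ratios(filter_sites(co$dataset)$dataset))
  norm <- rank_normal(ratios)
  sel <- select_features(norm, co$samples$age_years, threshold = 0.5)
  pc <- pca_project(norm[sel$site, , drop = FALSE])
  expect_gte(abs(cor(pc$scores[, 1], co$samples$age_years)), 0.8)
})

test_that("Benjamini-Hochberg step-up arithmetic and monotonicity hold", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  set.seed(55)
  p <- runif(50)
  q <- p.adjust(p, method = "BH")
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("site-wise sex models flag planted male-specific slopes and skip single-sex data", {
  set.seed(57)
  n <- 40
  sex <- rep(c("F", "M"), each = n / 2)
  dnam <- runif(n, 0, 50)
  x <- matrix(rnorm(20 * n, 0.5, 0.05), 20, n,
              dimnames = list(sprintf("chr1:%d", 1:20 * 10), NULL))
  x[1, sex == "M"] <- x[1, sex == "M"] + 0.02 * dnam[sex == "M"]  # male-only slope
  pred <- data.frame(sample_id = sprintf("s%d", 1:n), age_years = dnam,
                     dnam_age = dnam + rnorm(n), sex = sex)
  res <- sitewise_sex_model(x, pred)
  expect_false(res$skipped)
  expect_true(res$table$flagged[res$table$site == "chr1:10"])
  expect_lte(res$n_flagged, 3L)
  expect_true(is.finite(res$delta_sex_p))

  single <- pred; single$sex <- "F"
  expect_message(r2 <- sitewise_sex_model(x, single), "skipped")
  expect_true(r2$skipped)
})
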