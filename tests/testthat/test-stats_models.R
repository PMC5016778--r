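test_that("pearson matches cor.test and is symmetric and affine-equivariant", {
  set.seed(2)
  x <- rnorm(15); y <- 0.5 * x + rnorm(15)
  a <- pearson_cor(x, y)
  ct <- cor.test(x, y)
  expect_equal(a$r, unname(ct$estimate))
  expect_equal(a$t, unname(ct$statistic))
  expect_equal(a$p, ct$p.value)
  expect_equal(a$df, 13)
  expect_equal(pearson_cor(y, x)$r, a$r)
  expect_equal(pearson_cor(3 * x + 2, y)$r, a$r)
  expect_equal(pearson_cor(-2 * x, y)$r, -a$r)
  expect_error(pearson_cor(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("perfect correlation gives r = 1 and vanishing p", {
  x <- 1:10
  a <- pearson_cor(x, x)
  expect_equal(a$r, 1)
  expect_equal(a$p, 0)
})

test_that("permutation p agrees with the exhaustive oracle at small n", {
  set.seed(9)
  x <- rnorm(7); y <- rnorm(7) + 0.5 * x
  p_exact <- exhaustive_perm_p(x, y)
  a <- pearson_cor(x, y, n_perm = 20000, seed = 4)
  mc_err <- 3 * sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(a$p_perm - p_exact), mc_err + 2 / 20001)
  # and the t-based p is in the same range at this n
  expect_lt(abs(a$p - p_exact), 0.05)
})

test_that("Bonferroni thresholds and flags follow alpha / m", {
  b <- bonferroni(c(0.0019, 0.02, NA), m = 12)
  expect_equal(b$threshold, 0.05 / 12)
  expect_equal(round(b$threshold, 4), 0.0042)
  expect_identical(b$significant, c(TRUE, FALSE, FALSE))
  expect_true(bonferroni(0.001, m = 1)$significant)
  expect_error(bonferroni(1.2, m = 3), "\\[0, 1\\]")
})

test_that("MLR coefficients match the normal-equations oracle", {
  d <- random_study_df(20, seed = 31)
  preds <- c("status_local", "aquaculture", "substrate", "traffic")
  m <- fit_mlr(d, "nis_prop", preds)
  X <- cbind(1, as.matrix(d[preds]))
  beta <- ols_normal_equations(X, d$nis_prop)
  expect_equal(unname(coef(m)), unname(beta), tolerance = 1e-10)
  expect_equal(m$R2, m$R^2)
  expect_equal(m$df2, 20 - 4 - 1)
  expect_equal(unname(predict(m)), unname(drop(X %*% beta)), tolerance = 1e-10)
  expect_equal(unname(residuals(m)), unname(d$nis_prop - drop(X %*% beta)),
               tolerance = 1e-10)
})

test_that("single-predictor MLR has t^2 equal to the overall F", {
  d <- random_study_df(18, seed = 5)
  m <- fit_mlr(d, "nis_prop", "aquaculture")
  t_slope <- m$coefficients["aquaculture", "t value"]
  expect_equal(t_slope^2, m$F, tolerance = 1e-10)
  expect_equal(m$df1, 1)
})

test_that("MLR flags perfect fits and names collinear columns", {
  d <- random_study_df(12, seed = 8)
  d$nis_prop <- 0.1 + 0.05 * d$aquaculture  # exact linear response
  m <- suppressWarnings(fit_mlr(d, "nis_prop", "aquaculture"))
  expect_true(m$perfect_fit)
  expect_equal(m$F, Inf)
  expect_equal(m$R2, 1)

  d2 <- random_study_df(12, seed = 8)
  d2$dup <- 2 * d2$aquaculture
  expect_error(fit_mlr(d2, "nis_prop", c("aquaculture", "dup")), "dup")
  expect_error(fit_mlr(random_study_df(4), "nis_prop",
                       c("aquaculture", "substrate", "traffic")), "n > k")
})

test_that("identity-link GLM reproduces the OLS line, G is nonnegative", {
  d <- random_study_df(25, seed = 13)
  g <- fit_glm_normal(d$aquaculture, d$nis_prop)
  ols <- lm(nis_prop ~ aquaculture, d)
  expect_equal(g$slope, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(g$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
  expect_gte(g$G, 0)
  expect_equal(g$phi, sum(resid(ols)^2) / (25 - 2), tolerance = 1e-10)
})

test_that("identity-link G orders fits like the OLS F", {
  set.seed(40)
  x <- rnorm(30)
  stats <- t(sapply(c(0, 0.3, 0.8, 1.5), function(b) {
    y <- 1 + b * x + rnorm(30, sd = 0.8)
    g <- fit_glm_normal(x, y)
    f <- summary(lm(y ~ x))$fstatistic[1]
    c(G = g$G, F = unname(f))
  }))
  expect_identical(order(stats[, "G"]), order(stats[, "F"]))
})

test_that("log-link GLM recovers an exponential mean curve within 2 SE", {
  set.seed(77)
  x <- runif(200, 0, 2)
  y <- exp(0.5 + 0.9 * x) + rnorm(200, sd = 0.3)
  g <- fit_glm_normal(x, y, link = "log")
  se <- summary(g$fit)$coefficients[, "Std. Error"]
  expect_lt(abs(g$intercept - 0.5), 2 * se[1])
  expect_lt(abs(g$slope - 0.9), 2 * se[2])
  expect_lt(g$p_slope, 1e-6)
})

test_that("Durbin-Watson hits its limits and bounds", {
  alt <- rep(c(1, -1), 10)
  expect_equal(durbin_watson(alt, n_perm = 0)$statistic, 4 * 19 / 20)
  expect_equal(durbin_watson(rep(1, 10), n_perm = 0)$statistic, 0)
  expect_error(durbin_watson(rep(0, 10)), "zero residual")
  set.seed(12)
  for (i in 1:20) {
    s <- durbin_watson(rnorm(sample(5:40, 1)), n_perm = 0)$statistic
    expect_gte(s, 0); expect_lte(s, 4)
  }
})

test_that("Durbin-Watson permutation null is centred near 2", {
  set.seed(30)
  sims <- replicate(300, durbin_watson(rnorm(25), n_perm = 0)$statistic)
  expect_equal(mean(sims), 2, tolerance = 0.1)
  # strongly autocorrelated residuals are detected
  e <- as.numeric(stats::filter(rnorm(40), 0.95, "recursive"))
  dwp <- durbin_watson(e, n_perm = 499, seed = 2)
  expect_lt(dwp$p, 0.05)
  expect_lt(dwp$statistic, 1)
})

test_that("Durbin-Watson statistic agrees with the lmtest implementation", {
  skip_if_not_installed("lmtest")
  d <- packaged_table1()
  f <- lm(nis_prop ~ richness, as.data.frame(d))
  expect_equal(durbin_watson(resid(f), n_perm = 0)$statistic,
               unname(lmtest::dwtest(f)$statistic), tolerance = 1e-10)
})

test_that("Breusch-Pagan matches lmtest and degenerates to zero", {
  set.seed(14)
  x <- runif(60); y <- 1 + x + rnorm(60, sd = 0.2 + 0.5 * x)
  f <- lm(y ~ x)
  bp <- breusch_pagan(x, resid(f))
  expect_equal(bp$df, 1)
  skip_if_not_installed("lmtest")
  ref <- lmtest::bptest(f)  # studentized LM form = n R^2 of aux regression
  expect_equal(bp$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(bp$p, unname(ref$p.value), tolerance = 1e-8)
  expect_equal(breusch_pagan(x, rep(0.3, 60))$statistic, 0)
})

test_that("Breusch-Pagan has power against variance growing with x", {
  hits <- 0
  for (i in 1:50) {
    set.seed(1000 + i)
    x <- runif(200, 0.5, 2)
    y <- 1 + x + rnorm(200, sd = 0.3 * x^2)
    bp <- breusch_pagan(x, resid(lm(y ~ x)))
    if (bp$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.8)
})
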