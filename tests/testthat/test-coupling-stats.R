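test_that("pearson_corr matches the product-moment formula and limits", {
  x <- annual_series(2000:2009, rnorm(10))
  y1 <- annual_series(2000:2009, 2 * x$values + 1)
  expect_equal(pearson_corr(x, y1)$r, 1, tolerance = 1e-12)
  y2 <- annual_series(2000:2009, -x$values)
  expect_equal(pearson_corr(x, y2)$r, -1, tolerance = 1e-12)

  a <- c(1, 2, 3, 4); b <- c(1, 2, 2, 4)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_corr(a, b)$r, hand, tolerance = 1e-14)
  expect_error(pearson_corr(a, rep(1, 4)), "variance")
})

test_that("correlation is symmetric and scale invariant", {
  set.seed(1)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearson_corr(x, y)$r, pearson_corr(y, x)$r)
  expect_equal(pearson_corr(3 * x + 5, -0.1 * y)$r,
               -pearson_corr(x, y)$r, tolerance = 1e-12)
})

test_that("partial correlation handles constructed orthogonal and
           fully-explained cases", {
  # z exactly uncorrelated with both x and y: partial equals plain r
  x <- c(1, -1, 1, -1, 2, -2, 2, -2)
  z <- c(1, 1, -1, -1, 1, 1, -1, -1)
  y <- c(2, -2, 1, -1, 3, -3, 1, -1)
  stopifnot(cor(x, z) == 0, cor(y, z) == 0)
  expect_equal(partial_corr(x, y, z)$r, cor(x, y), tolerance = 1e-12)
  # y identical to the control: nothing left to correlate
  expect_equal(partial_corr(x, z, z)$r, 0)
})

test_that("partial-correlation formula equals the residual-regression
           oracle on random triples", {
  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(20); z <- rnorm(20)
    y <- 0.5 * x + 0.3 * z + rnorm(20)
    expect_equal(partial_corr(x, y, z)$r, partial_oracle(x, y, z),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap of degenerate-free statistics behaves analytically", {
  const <- annual_series(2000:2009, rep(4.2, 10))
  bs <- bootstrap_stat(function(m) mean(m[, 1]), list(x = const),
                       n_reps = 200, seed = 1)
  expect_true(all(bs$replicates == 4.2))
  expect_equal(unname(bs$ci), c(4.2, 4.2))

  x <- annual_series(2000:2011, rnorm(12))
  bs1 <- bootstrap_stat(function(m) .subset2(stats::cor(m), 2),
                        list(x = x, y = x), n_reps = 500, seed = 2)
  expect_true(all(abs(bs1$replicates - 1) < 1e-12))
})

test_that("bootstrap standard error of the mean tracks sigma/sqrt(n)", {
  vals <- c(3.1, -0.4, 2.2, 5.9, -1.3, 0.8, 4.4, 2.0, -2.5, 1.7)
  s <- annual_series(2001:2010, vals)
  bs <- bootstrap_stat(function(m) mean(m[, 1]), list(x = s),
                       n_reps = 5000, seed = 3, statistic_name = "mean")
  analytic <- sqrt(mean((vals - mean(vals))^2)) / sqrt(length(vals))
  expect_lt(abs(sd(bs$replicates) - analytic) / analytic, 0.15)
})

test_that("bootstrap is reproducible under a fixed seed", {
  x <- annual_series(2000:2019, rnorm(20))
  y <- annual_series(2000:2019, rnorm(20))
  f <- function(m) cor(m[, 1], m[, 2])
  b1 <- bootstrap_stat(f, list(x = x, y = y), 300, seed = 9)
  b2 <- bootstrap_stat(f, list(x = x, y = y), 300, seed = 9)
  expect_identical(b1$replicates, b2$replicates)
})

test_that("percentile interval coverage is near nominal on Gaussian data", {
  set.seed(21)
  hit <- logical(200)
  for (i in seq_along(hit)) {
    s <- annual_series(1:30 + 1999, rnorm(30, mean = 1))
    bs <- bootstrap_stat(function(m) mean(m[, 1]), list(x = s),
                         n_reps = 1000, seed = i)
    hit[i] <- bs$ci[1] <= 1 && 1 <= bs$ci[2]
  }
  expect_gt(mean(hit), 0.87)  # within a few points of the 95% level
})

test_that("change significance is 1 for identical results and tiny for
           disjoint supports", {
  x <- annual_series(2000:2019, rnorm(20))
  f <- function(m) mean(m[, 1])
  a <- bootstrap_stat(f, list(x = x), 400, seed = 5, statistic_name = "mean")
  expect_equal(change_significance(a, a), list(delta = 0, p = 1))

  b <- a
  b$replicates <- a$replicates + 100
  b$point_estimate <- a$point_estimate + 100
  chg <- change_significance(a, b)
  expect_equal(chg$delta, 100)
  expect_lte(chg$p, 2 / a$n_reps)

  c2 <- a; c2$statistic_name <- "other"
  expect_error(change_significance(a, c2), "different statistics")
})

test_that("OLS sensitivity recovers exact slopes", {
  x <- annual_series(2000:2014, rnorm(15))
  y <- annual_series(2000:2014, -1.2 * x$values)
  est <- ols_sensitivity(y, x, n_reps = 200, seed = 1)
  expect_equal(est$gamma, -1.2, tolerance = 1e-12)
  expect_equal(est$model_kind, "univariate_ols")
  expect_equal(est$regularization, 0)

  xs <- annual_series(2000:2014, scale(rnorm(15))[, 1])
  ys <- annual_series(2000:2014, xs$values)
  expect_equal(ols_sensitivity(ys, xs, 200, 1)$gamma, 1, tolerance = 1e-12)
  expect_error(ols_sensitivity(y, annual_series(2000:2014, rep(2, 15))),
               "variance")
})

test_that("ridge at lambda 0 equals bivariate OLS", {
  set.seed(31)
  yrs <- 1990:2019
  x1 <- annual_series(yrs, rnorm(30))
  x2 <- annual_series(yrs, 0.6 * x1$values + 0.8 * rnorm(30))
  y <- annual_series(yrs, -1 * x1$values + 2 * x2$values + rnorm(30))
  rp <- ridge_sensitivity(y, x1, x2, n_reps = 100, seed = 1, lambda = 0)
  ols <- stats::coef(stats::lm(y$values ~ x1$values + x2$values))
  expect_equal(rp$x1$gamma, unname(ols[2]), tolerance = 1e-10)
  expect_equal(rp$x2$gamma, unname(ols[3]), tolerance = 1e-10)
  rp2 <- ridge_sensitivity(y, x1, x2, n_reps = 100, seed = 1, mode = "ols")
  expect_equal(rp2$x1$gamma, unname(ols[2]), tolerance = 1e-10)
  expect_equal(rp2$x1$model_kind, "bivariate_ols")
})

test_that("fixed-lambda ridge equals the closed form on standardized
           predictors", {
  set.seed(32)
  yrs <- 1990:2014
  x1 <- rnorm(25); x2 <- 0.7 * x1 + rnorm(25); y <- x1 - x2 + rnorm(25)
  lam <- 3.7
  rp <- ridge_sensitivity(annual_series(yrs, y), annual_series(yrs, x1),
                          annual_series(yrs, x2), n_reps = 100, seed = 1,
                          lambda = lam)
  X <- scale(cbind(x1, x2))
  beta <- solve(crossprod(X) + diag(lam, 2), crossprod(X, y - mean(y)))
  expect_equal(rp$x1$gamma, beta[1] / sd(x1), tolerance = 1e-10)
  expect_equal(rp$x2$gamma, beta[2] / sd(x2), tolerance = 1e-10)
  expect_equal(rp$x1$regularization, lam)
})

test_that("ridge coefficient norm shrinks monotonically with the penalty", {
  set.seed(33)
  yrs <- 1990:2019
  x1 <- annual_series(yrs, rnorm(30))
  x2 <- annual_series(yrs, 0.8 * x1$values + 0.6 * rnorm(30))
  y <- annual_series(yrs, x1$values + x2$values + rnorm(30))
  norms <- sapply(c(0, 0.1, 1, 10, 100), function(l) {
    rp <- ridge_sensitivity(y, x1, x2, n_reps = 10, seed = 1, lambda = l)
    # norm on the standardized scale, where the penalty acts
    sqrt((rp$x1$gamma * sd(x1$values))^2 + (rp$x2$gamma * sd(x2$values))^2)
  })
  expect_true(all(diff(norms) < 0))
})

test_that("ridge matches an independent solver at a fixed penalty", {
  skip_if_not_installed("glmnet")
  set.seed(34)
  yrs <- 1980:2019
  x1 <- rnorm(40); x2 <- 0.6 * x1 + rnorm(40)
  y <- -x1 + 2 * x2 + rnorm(40)
  lam <- 2.5
  rp <- ridge_sensitivity(annual_series(yrs, y), annual_series(yrs, x1),
                          annual_series(yrs, x2), n_reps = 10, seed = 1,
                          lambda = lam)
  X <- scale(cbind(x1, x2))
  # glmnet minimizes RSS/(2n) + lambda_g/2 * ||beta||^2 after scaling the
  # response by its population s.d., so lambda_g = lam/n * popsd(y)
  popsd <- sqrt(mean((y - mean(y))^2))
  g <- glmnet::glmnet(X, y, alpha = 0,
                      lambda = lam / length(y) * popsd,
                      standardize = FALSE, intercept = TRUE,
                      thresh = 1e-20, maxit = 1e7)
  bg <- as.numeric(stats::coef(g))[-1]
  expect_equal(rp$x1$gamma, bg[1] / sd(x1), tolerance = 1e-6)
  expect_equal(rp$x2$gamma, bg[2] / sd(x2), tolerance = 1e-6)
})

test_that("perfectly collinear predictors warn under ridge and error under
           OLS", {
  yrs <- 2000:2019
  x1 <- annual_series(yrs, rnorm(20))
  x2 <- annual_series(yrs, 2 * x1$values)
  y <- annual_series(yrs, x1$values + rnorm(20))
  expect_warning(ridge_sensitivity(y, x1, x2, n_reps = 10, seed = 1,
                                   lambda = 1), "collinear")
  expect_error(suppressWarnings(
    ridge_sensitivity(y, x1, x2, n_reps = 10, seed = 1, mode = "ols")),
    "collinear")
})

test_that("a single full-span window reproduces full-period statistics", {
  cf <- synth_config(1980, 2009, seed = 8)
  ds <- generate_study_dataset(cf)
  bundle <- pipeline_bundle(ds)
  wa <- window_analysis(bundle, list(c(1980, 2009)), n_reps = 200,
                        seed = 1, ridge = FALSE)
  sub <- lapply(lapply(bundle, window_series, window = c(1980, 2009)),
                detrend_linear)
  direct <- pearson_corr(sub$ws, sub$cgr)
  expect_equal(wa$estimate[wa$statistic == "r_ws_cgr"], direct$r,
               tolerance = 1e-12)
  expect_equal(wa$p_value[wa$statistic == "r_ws_cgr"], direct$p,
               tolerance = 1e-12)
  expect_error(window_analysis(bundle, list(c(1900, 1950))), "outside")
})

test_that("moving window with width equal to the span gives the full-period
           value", {
  cf <- synth_config(1980, 2009, seed = 9)
  ds <- generate_study_dataset(cf)
  bundle <- pipeline_bundle(ds)
  mw <- moving_window(bundle, width = 30, stat = "r_ws_cgr")
  expect_equal(nrow(mw), 1L)
  sub <- lapply(bundle, detrend_linear)
  expect_equal(mw$value, pearson_corr(sub$ws, sub$cgr)$r, tolerance = 1e-12)
  expect_error(moving_window(bundle, width = 3), "at least 5")
  expect_error(moving_window(bundle, width = 31), "exceeds")
})
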