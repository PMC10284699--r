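make_co2 <- function(years, fun) {
  g <- expand.grid(month = 1:12, year = years)[, 2:1]
  g$co2_ppm <- fun(g$year, g$month)
  g
}

test_that("CGR of a linear ramp is the ramp slope, and zero for constant", {
  co2 <- make_co2(2000:2005, function(y, m) 340 + 2 * (y - 2000 + m / 12))
  cgr <- annual_cgr_from_monthly_co2(co2, convert = FALSE)
  expect_false(cgr$valid[1])  # no preceding December
  expect_equal(cgr$values[cgr$valid], rep(2, 5), tolerance = 1e-12)

  flat <- make_co2(2000:2003, function(y, m) 380)
  cgr0 <- annual_cgr_from_monthly_co2(flat, convert = FALSE)
  expect_equal(cgr0$values[cgr0$valid], rep(0, 3))
})

test_that("incomplete years are flagged invalid, not dropped", {
  co2 <- make_co2(2000:2002, function(y, m) 340 + y - 2000)
  co2 <- co2[!(co2$year == 2001 & co2$month == 5), ]
  cgr <- annual_cgr_from_monthly_co2(co2)
  expect_equal(cgr$years, 2000:2002)
  # 2001 incomplete; 2002 needs a complete 2001 for its December anchor
  expect_equal(cgr$valid, c(FALSE, FALSE, FALSE))
})

test_that("ppm to PgC conversion applies the configured constant", {
  co2 <- make_co2(2000:2002, function(y, m) 340 + 2 * (y - 2000 + m / 12))
  cgr <- annual_cgr_from_monthly_co2(co2, pgc_per_ppm = 2.124)
  expect_equal(cgr$values[cgr$valid], rep(4.248, 2), tolerance = 1e-12)
})

test_that("detrending removes exact lines and reproduces OLS residuals", {
  yrs <- 2000:2004
  expect_equal(detrend_linear(annual_series(yrs, 3 * yrs - 12))$values,
               rep(0, 5), tolerance = 1e-9)
  expect_equal(detrend_linear(annual_series(yrs, rep(7, 5)))$values,
               rep(0, 5), tolerance = 1e-12)
  # quadratic (0,1,4,9,16): best line 4x - 6 over x=1..5, residuals frozen
  s <- detrend_linear(annual_series(yrs, c(0, 1, 4, 9, 16)))
  expect_equal(s$values, c(2, -1, -2, -1, 2), tolerance = 1e-10)
})

test_that("detrending is idempotent and fits on valid years only", {
  set.seed(42)
  s <- annual_series(1960:2000, cumsum(rnorm(41)) + 0.3 * (0:40))
  d1 <- detrend_linear(s)
  expect_equal(detrend_linear(d1)$values, d1$values, tolerance = 1e-10)
  # an extreme invalid year must not tilt the fitted trend: anomalies at
  # valid years equal those of the series with that year removed entirely
  v <- s$values; v[10] <- 1e3
  sv <- annual_series(s$years, v, valid = seq_along(v) != 10)
  dv <- detrend_linear(sv)
  ref <- detrend_linear(annual_series(s$years[-10], s$values[-10]))
  expect_equal(dv$values[-10], ref$values, tolerance = 1e-9)
  expect_error(detrend_linear(annual_series(1:3, 1:3, valid = c(TRUE, TRUE,
                                                                FALSE))),
               "3 valid")
})

test_that("gridded detrending works per cell", {
  A <- cbind(2 * (1:6), seq(3, 13, by = 2), rnorm(6))
  f <- field_from_matrix(A, 1, 3)
  d <- detrend_linear(f)
  expect_equal(d$values[, 1, 1], rep(0, 6), tolerance = 1e-12)
  expect_equal(d$values[, 1, 2], rep(0, 6), tolerance = 1e-12)
  expect_equal(d$values[, 1, 3],
               unname(stats::residuals(stats::lm(A[, 3] ~ I(1:6)))),
               tolerance = 1e-10)
})

test_that("volcano-year exclusion clears the validity flag", {
  s <- annual_series(1960:1965, 1:6)
  e <- exclude_volcano_years(s)
  expect_equal(sum(e$valid), 4L)
  expect_false(any(e$valid[e$years %in% c(1963, 1964)]))
  expect_equal(exclude_volcano_years(s, integer())$valid, s$valid)
  all_out <- exclude_volcano_years(s, 1960:1965)
  expect_error(detrend_linear(all_out), "valid")
})

test_that("tropical aggregation handles constants, masks and weights", {
  A <- matrix(5, 4, 6)  # 4 years, 6 cells
  f <- field_from_matrix(A, 2, 3)
  agg <- area_weighted_tropical_mean(f)
  expect_equal(agg$values, rep(5, 4))

  # single-cell mask returns that cell's series
  B <- matrix(rnorm(24), 4, 6)
  fb <- field_from_matrix(B, 2, 3)
  m <- matrix(FALSE, 2, 3); m[2, 1] <- TRUE
  expect_equal(area_weighted_tropical_mean(fb, mask = m)$values,
               array(fb$values, c(4, 6))[, 2])

  # hand-computed cos-latitude weights at 0 and 60 degrees
  f2 <- gridded_field(array(c(1, 0), c(1, 2, 1)), c(0, 60), 10, 2000)
  got <- area_weighted_tropical_mean(f2, band = c(-90, 90))
  expect_equal(got$values, cos(0) / (cos(0) + cos(pi / 3)), tolerance = 1e-12)
  expect_equal(got$values, 2 / 3, tolerance = 1e-12)
})

test_that("aggregation commutes with zeroing cells outside the mask", {
  set.seed(7)
  B <- matrix(rnorm(40), 5, 8)
  m <- matrix(c(TRUE, FALSE), 2, 4)
  f1 <- field_from_matrix(B, 2, 4, mask = m)
  Bz <- B; Bz[, !as.vector(m)] <- 0
  f2 <- field_from_matrix(Bz, 2, 4, mask = m)
  expect_equal(area_weighted_tropical_mean(f1)$values,
               area_weighted_tropical_mean(f2)$values, tolerance = 1e-12)
})

test_that("mass-sum mode converts uniform mm to the analytic Tt total", {
  lat <- seq(-21, 21, by = 6); lon <- seq(11.25, 348.75, length.out = 16)
  f <- gridded_field(array(1, c(2, 8, 16)), lat, lon, 2000:2001)
  agg <- area_weighted_tropical_mean(f, mode = "sum")
  analytic <- 2 * pi * 6371000^2 * 2 * sin(24 * pi / 180) / 1e15
  expect_equal(agg$values, rep(analytic, 2), tolerance = 1e-12)
  expect_equal(agg$units, "Tt H2O")
})

test_that("LagP sums July through June and flags the first year", {
  p <- expand.grid(month = 1:12, year = 2000:2003)[, 2:1]
  p$value <- 10
  lp <- lagged_annual_precip(p)
  expect_false(lp$valid[1])
  expect_equal(lp$values[lp$valid], rep(120, 3))

  p$value <- ifelse(p$year == 2001 & p$month == 7, 1, 0)
  imp <- lagged_annual_precip(p)
  expect_equal(imp$values[imp$years == 2002], 1)
  expect_equal(imp$values[imp$valid & imp$years != 2002],
               rep(0, 2))
})

test_that("gridded LagP matches a brute-force 12-month window sum", {
  cf <- synth_config(2000, 2009, grid_shape = c(3, 4), seed = 5)
  ds <- generate_study_dataset(cf)
  lp <- lagged_annual_precip(ds$precip)
  # oracle: aggregate each month spatially, then sum the window directly
  d <- dim(ds$precip$values)
  w <- rep(cos_lat_weights(ds$precip$lat), d[3])
  monthly <- drop(matrix(ds$precip$values, d[1], d[2] * d[3]) %*% w) / sum(w)
  for (y in c(2003, 2007)) {
    idx <- which((ds$precip$years == y - 1 & ds$precip$months >= 7) |
                 (ds$precip$years == y & ds$precip$months <= 6))
    expect_equal(lp$values[lp$years == y], sum(monthly[idx]),
                 tolerance = 1e-10)
  }
})
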