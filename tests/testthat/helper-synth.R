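# small fixtures and independent oracles shared across test files

# yearly gridded field from a (years x cells) matrix on an n_lat x n_lon grid
field_from_matrix <- function(A, n_lat, n_lon, years = NULL,
                              lat = NULL, lon = NULL, mask = NULL) {
  if (is.null(years)) years <- seq(2000, length.out = nrow(A))
  if (is.null(lat)) lat <- seq(-20, 20, length.out = n_lat)
  if (is.null(lon)) lon <- seq(10, 350, length.out = n_lon)
  gridded_field(array(A, c(nrow(A), n_lat, n_lon)), lat, lon, years,
                mask = mask)
}

# explicit pairwise double-loop coherence over a period (years x cells)
coherence_oracle_period <- function(A) {
  nc <- ncol(A)
  signed <- 0; absum <- 0
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    if (i == j) next
    cij <- stats::cov(A[, i], A[, j])
    signed <- signed + cij
    absum <- absum + abs(cij)
  }
  100 * signed / absum
}

# explicit pairwise double loop on a single year's cell anomalies
coherence_oracle_year <- function(x) {
  n <- length(x)
  signed <- 0; absum <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    signed <- signed + x[i] * x[j]
    absum <- absum + abs(x[i] * x[j])
  }
  100 * signed / absum
}

# partial correlation via explicit residual regressions
partial_oracle <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# detrended water/temperature/CGR bundle from a generated study dataset
pipeline_bundle <- function(ds, volcano = FALSE, lagp = FALSE) {
  cgr <- annual_cgr_from_monthly_co2(ds$co2_monthly)
  if (volcano) cgr <- exclude_volcano_years(cgr)
  out <- list(cgr = cgr,
              ws = area_weighted_tropical_mean(ds$ws, mode = "sum"),
              temp = area_weighted_tropical_mean(ds$temp, mode = "mean"))
  if (lagp) out$lagp <- lagged_annual_precip(ds$precip)
  out
}

# an evenly spread, time-stationary event calendar
stationary_schedule <- function(years) {
  rep_len(c("EP", "NEUTRAL", "NEUTRAL", "CP", "NEUTRAL", "NEUTRAL"),
          length(years))
}
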