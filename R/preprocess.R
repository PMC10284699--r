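#' Default conversion between atmospheric CO2 concentration and carbon mass
#'
#' One ppm of atmospheric CO2 corresponds to about 2.124 PgC; the constant
#' is exposed so analyses (and tests) can override it.
#' @export
PGC_PER_PPM <- 2.124

#' Years conventionally excluded after major volcanic eruptions
#'
#' Agung (1963-1964), El Chichon (1982) and Pinatubo (1991-1993) perturbed
#' the global carbon balance through unusual flux anomalies; interannual
#' coupling analyses drop these years.
#' @export
VOLCANO_YEARS <- c(1963L, 1964L, 1982L, 1991L, 1992L, 1993L)

#' Annual CO2 growth rate from a monthly concentration series
#'
#' The growth rate of year y is the concentration difference across that
#' year. On monthly-mean data the operational rule is
#' `CGR(y) = Dec(y) - Dec(y-1)`; the first year, which has no preceding
#' December, is flagged invalid rather than dropped. Years with incomplete
#' monthly coverage are likewise flagged invalid.
#'
#' @param co2 data frame with columns `year`, `month`, `co2_ppm`.
#' @param convert if `TRUE` (default) convert ppm/yr to PgC/yr.
#' @param pgc_per_ppm conversion constant, PgC per ppm.
#' @return An [annual_series()] of CGR, in PgC/yr (or ppm/yr).
#' @export
annual_cgr_from_monthly_co2 <- function(co2, convert = TRUE,
                                        pgc_per_ppm = PGC_PER_PPM) {
  stopifnot(all(c("year", "month", "co2_ppm") %in% names(co2)))
  yrs <- sort(unique(co2$year))
  complete <- vapply(yrs, function(y)
    setequal(co2$month[co2$year == y], 1:12), logical(1))
  dec <- vapply(yrs, function(y) {
    v <- co2$co2_ppm[co2$year == y & co2$month == 12L]
    if (length(v) == 1L) v else NA_real_
  }, numeric(1))
  cgr <- c(NA_real_, diff(dec))
  valid <- complete & c(FALSE, complete[-length(complete)]) & is.finite(cgr)
  if (convert) cgr <- cgr * pgc_per_ppm
  annual_series(yrs, cgr, units = if (convert) "PgC yr-1" else "ppm yr-1",
                valid = valid)
}

#' Remove the long-term linear trend
#'
#' Fits an ordinary least-squares line against calendar year (or time
#' index) and returns the residual anomalies. For annual series the line is
#' fitted on valid years only; anomalies of invalid years are still
#' computed (relative to the fitted line) but stay flagged invalid. For
#' gridded fields every cell is detrended independently against its time
#' index.
#'
#' @param x an [annual_series()], [gridded_field()] or numeric vector.
#' @param ... unused.
#' @return Object of the same type holding anomalies.
#' @export
detrend_linear <- function(x, ...) UseMethod("detrend_linear")

#' @export
detrend_linear.annual_series <- function(x, ...) {
  ok <- x$valid
  if (sum(ok) < 3L)
    stop("detrending needs at least 3 valid years", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x$years[ok]), x$values[ok])
  pred <- cbind(1, x$years) %*% fit$coefficients
  annual_series(x$years, x$values - drop(pred), x$units, x$valid)
}

#' @export
detrend_linear.numeric <- function(x, ...) {
  if (length(x) < 3L) stop("detrending needs at least 3 points", call. = FALSE)
  t <- seq_along(x)
  drop(stats::lm.fit(cbind(1, t), x)$residuals)
}

#' @export
detrend_linear.gridded_field <- function(x, ...) {
  d <- dim(x$values)
  if (d[1L] < 3L) stop("detrending needs at least 3 time steps", call. = FALSE)
  t <- seq_len(d[1L])
  X <- cbind(1, t)
  flat <- matrix(x$values, d[1L], d[2L] * d[3L])
  res <- flat - X %*% qr.coef(qr(X), flat)
  gridded_field(array(res, d), x$lat, x$lon, x$years, x$months,
                x$units, x$mask)
}

#' Flag post-eruption years invalid
#'
#' @param s an [annual_series()].
#' @param volcano_years integer years to invalidate; defaults to
#'   [VOLCANO_YEARS].
#' @return The series with the listed years flagged invalid.
#' @export
exclude_volcano_years <- function(s, volcano_years = VOLCANO_YEARS) {
  valid <- s$valid & !(s$years %in% volcano_years)
  annual_series(s$years, s$values, s$units, valid)
}

#' Tropical aggregate of a gridded field
#'
#' Aggregates a (monthly or yearly) field over the vegetated tropical band
#' into one annual series. Monthly inputs are first collapsed to yearly
#' values per cell (`annual = "mean"` for states such as water storage or
#' temperature, `"sum"` for fluxes such as precipitation). Spatially,
#' `mode = "mean"` returns the cos-latitude-weighted (or unweighted) mean
#' in the field's units, while `mode = "sum"` converts a water depth in mm
#' to a total stored mass in teratonnes of water (Tt H2O) using spherical
#' cell areas, the unit in which CGR-to-water sensitivities are expressed.
#'
#' @param f a [gridded_field()].
#' @param mask optional vegetated-land mask (logical matrix or
#'   `gridded_field`), intersected with the field's own mask.
#' @param band latitude limits, default the 24S-24N tropical belt.
#' @param mode `"mean"` or `"sum"` (mm -> Tt H2O).
#' @param annual monthly-to-yearly collapse, `"mean"` or `"sum"`.
#' @param weighted use cos-latitude weights for `mode = "mean"`.
#' @return An [annual_series()].
#' @export
area_weighted_tropical_mean <- function(f, mask = NULL, band = c(-24, 24),
                                        mode = c("mean", "sum"),
                                        annual = c("mean", "sum"),
                                        weighted = TRUE) {
  mode <- match.arg(mode)
  annual <- match.arg(annual)
  fy <- annual_field(f, annual)
  m <- effective_mask(fy, mask, band)
  if (!any(m)) stop("no unmasked cells inside the latitude band",
                    call. = FALSE)
  d <- dim(fy$values)
  flat <- matrix(fy$values, d[1L], d[2L] * d[3L])[, as.vector(m), drop = FALSE]
  if (mode == "mean") {
    w <- if (weighted) {
      matrix(cos_lat_weights(fy$lat), d[2L], d[3L])[m]
    } else rep(1, sum(m))
    vals <- drop(flat %*% w) / sum(w)
    units <- fy$units
  } else {
    areas <- cell_areas_m2(fy$lat, fy$lon)[m]
    # 1 mm water over 1 m^2 weighs 1 kg; 1 Tt = 1e15 kg
    vals <- drop(flat %*% areas) / 1e15
    units <- "Tt H2O"
  }
  annual_series(fy$years, vals, units)
}

#' Six-month lagged yearly precipitation (LagP)
#'
#' LagP of year y is the precipitation accumulated from July of year y-1
#' through June of year y, a proxy for the water actually stored and
#' available during year y. The first labelled year, which lacks a
#' preceding July, is flagged invalid.
#'
#' @param p either a monthly [gridded_field()] of precipitation (aggregated
#'   spatially with [area_weighted_tropical_mean()] conventions first) or a
#'   data frame with columns `year`, `month`, `value`.
#' @param mask,band,weighted passed to the spatial aggregation when `p` is
#'   gridded.
#' @return An [annual_series()] of LagP in the input's units per year.
#' @export
lagged_annual_precip <- function(p, mask = NULL, band = c(-24, 24),
                                 weighted = TRUE) {
  if (inherits(p, "gridded_field")) {
    if (!is_monthly(p)) stop("LagP needs monthly input", call. = FALSE)
    m <- effective_mask(p, mask, band)
    if (!any(m)) stop("no unmasked cells inside the latitude band",
                      call. = FALSE)
    d <- dim(p$values)
    w <- if (weighted) matrix(cos_lat_weights(p$lat), d[2L], d[3L])[m]
         else rep(1, sum(m))
    flat <- matrix(p$values, d[1L], d[2L] * d[3L])[, as.vector(m),
                                                   drop = FALSE]
    p <- data.frame(year = p$years, month = p$months,
                    value = drop(flat %*% w) / sum(w))
  }
  stopifnot(all(c("year", "month", "value") %in% names(p)))
  yrs <- sort(unique(p$year))
  val <- vapply(yrs, function(y) {
    idx <- (p$year == y - 1L & p$month >= 7L) |
           (p$year == y & p$month <= 6L)
    if (sum(idx) == 12L) sum(p$value[idx]) else NA_real_
  }, numeric(1))
  annual_series(yrs, val, units = "per year", valid = is.finite(val))
}
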