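#' Gridded (time, lat, lon) field
#'
#' Lightweight container for one variable on a regular latitude-longitude
#' grid, monthly or yearly. Masked cells are excluded from every spatial
#' aggregate computed by the package.
#'
#' @param values numeric array of dimension `(n_time, n_lat, n_lon)`.
#' @param lat,lon coordinate vectors in degrees; latitudes in `[-90, 90]`,
#'   longitudes on the 0--360 convention.
#' @param years integer vector of length `n_time`; the calendar year of each
#'   time step.
#' @param months integer vector of length `n_time` (1--12) for monthly
#'   fields, or `NULL` for yearly fields.
#' @param units character unit string carried through aggregations.
#' @param mask optional `n_lat x n_lon` logical matrix; `FALSE` cells are
#'   excluded from spatial statistics.
#'
#' @return An object of class `gridded_field`.
#' @export
gridded_field <- function(values, lat, lon, years, months = NULL,
                          units = "", mask = NULL) {
  values <- unclass(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-d array (time, lat, lon)", call. = FALSE)
  d <- dim(values)
  if (length(lat) != d[2L] || length(lon) != d[3L])
    stop("coordinate lengths do not match array dimensions", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitudes must lie in [-90, 90]", call. = FALSE)
  if (length(years) != d[1L])
    stop("`years` length does not match the time dimension", call. = FALSE)
  if (!is.null(months)) {
    if (length(months) != d[1L])
      stop("`months` length does not match the time dimension", call. = FALSE)
    if (any(months < 1L | months > 12L))
      stop("months must lie in 1..12", call. = FALSE)
  }
  if (!is.null(mask)) {
    mask <- matrix(as.logical(mask), d[2L], d[3L])
  }
  structure(
    list(values = values, lat = as.numeric(lat), lon = as.numeric(lon),
         years = as.integer(years),
         months = if (is.null(months)) NULL else as.integer(months),
         units = units, mask = mask),
    class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  d <- dim(x$values)
  cadence <- if (is.null(x$months)) "yearly" else "monthly"
  cat(sprintf("<gridded_field> %d x %d grid, %d %s steps (%d-%d)%s\n",
              d[2L], d[3L], d[1L], cadence, min(x$years), max(x$years),
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  if (!is.null(x$mask))
    cat(sprintf("  mask: %d of %d cells active\n", sum(x$mask), d[2L] * d[3L]))
  invisible(x)
}

is_monthly <- function(f) !is.null(f$months)

#' Year-indexed annual scalar series
#'
#' Container for a yearly scalar series (CGR, tropical aggregates, Nino
#' indices, ...) with a per-year validity flag. Invalid years (incomplete
#' coverage, volcano exclusion) are retained but excluded from every
#' downstream statistic.
#'
#' @param years strictly increasing integer vector of calendar years.
#' @param values numeric vector, same length as `years`.
#' @param units character unit string.
#' @param valid logical vector, same length as `years`.
#'
#' @return An object of class `annual_series`.
#' @export
annual_series <- function(years, values, units = "",
                          valid = rep(TRUE, length(years))) {
  years <- as.integer(years)
  if (length(values) != length(years) || length(valid) != length(years))
    stop("`years`, `values` and `valid` must have equal length", call. = FALSE)
  if (anyDuplicated(years) || is.unsorted(years))
    stop("`years` must be strictly increasing without duplicates",
         call. = FALSE)
  valid <- as.logical(valid) & is.finite(values)
  structure(list(years = years, values = as.numeric(values),
                 units = units, valid = valid),
            class = "annual_series")
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf("<annual_series> %d years (%d-%d), %d valid%s\n",
              length(x$years), min(x$years), max(x$years), sum(x$valid),
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.annual_series <- function(x, ...) {
  data.frame(year = x$years, value = x$values, valid = x$valid)
}

#' Restrict an annual series to a year window
#'
#' @param s an [annual_series()].
#' @param window numeric `c(start, end)` in calendar years, inclusive.
#' @return An `annual_series` covering only the window.
#' @export
window_series <- function(s, window) {
  keep <- s$years >= window[1] & s$years <= window[2]
  if (!any(keep)) stop("window lies outside the data span", call. = FALSE)
  annual_series(s$years[keep], s$values[keep], s$units, s$valid[keep])
}

# years valid in every series of a named list
jointly_valid_years <- function(series_list) {
  yrs <- Reduce(intersect, lapply(series_list, function(s) s$years[s$valid]))
  sort(yrs)
}

# matrix of jointly valid values, one column per series
joint_valid_matrix <- function(series_list) {
  yrs <- jointly_valid_years(series_list)
  m <- vapply(series_list,
              function(s) s$values[match(yrs, s$years)],
              numeric(length(yrs)))
  m <- matrix(m, nrow = length(yrs),
              dimnames = list(NULL, names(series_list)))
  attr(m, "years") <- yrs
  m
}

#' Area weights and cell areas for a regular grid
#'
#' `cos_lat_weights` returns the cosine-of-latitude weight per row;
#' `cell_areas_m2` returns the spherical surface area of every cell in
#' square metres, assuming regular spacing in both coordinates.
#'
#' @param lat,lon coordinate vectors in degrees.
#' @return `cos_lat_weights`: numeric vector; `cell_areas_m2`: an
#'   `n_lat x n_lon` matrix of areas (m^2).
#' @export
cos_lat_weights <- function(lat) cos(lat * pi / 180)

#' @rdname cos_lat_weights
#' @export
cell_areas_m2 <- function(lat, lon) {
  r_earth <- 6371000
  dlat <- if (length(lat) > 1L) abs(stats::median(diff(lat))) else 1
  dlon <- if (length(lon) > 1L) abs(stats::median(diff(lon))) else 1
  phi1 <- (lat - dlat / 2) * pi / 180
  phi2 <- (lat + dlat / 2) * pi / 180
  band <- r_earth^2 * (dlon * pi / 180) * (sin(phi2) - sin(phi1))
  matrix(band, length(lat), length(lon))
}

# logical n_lat x n_lon matrix combining field mask, user mask, latitude band
effective_mask <- function(f, mask = NULL, band = NULL) {
  d <- dim(f$values)
  m <- matrix(TRUE, d[2L], d[3L])
  if (!is.null(f$mask)) m <- m & f$mask
  if (!is.null(mask)) {
    if (inherits(mask, "gridded_field")) mask <- mask$values[1, , ]
    m <- m & matrix(as.logical(mask), d[2L], d[3L])
  }
  if (!is.null(band)) m <- m & (f$lat >= band[1] & f$lat <= band[2])
  m
}

#' Collapse a monthly field to yearly resolution
#'
#' Averages (or sums, for precipitation-like fluxes) the twelve monthly
#' values of each calendar year in every cell. Years with incomplete
#' monthly coverage are dropped.
#'
#' @param f a monthly [gridded_field()].
#' @param fun `"mean"` or `"sum"`.
#' @return A yearly `gridded_field`.
#' @export
annual_field <- function(f, fun = c("mean", "sum")) {
  fun <- match.arg(fun)
  if (!is_monthly(f)) return(f)
  tab <- table(f$years)
  yrs <- as.integer(names(tab)[tab == 12L])
  d <- dim(f$values)
  out <- array(NA_real_, c(length(yrs), d[2L], d[3L]))
  for (k in seq_along(yrs)) {
    idx <- which(f$years == yrs[k])
    sl <- f$values[idx, , , drop = FALSE]
    agg <- colSums(sl, dims = 1L)
    out[k, , ] <- if (fun == "mean") agg / length(idx) else agg
  }
  gridded_field(out, f$lat, f$lon, yrs, NULL, f$units, f$mask)
}
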