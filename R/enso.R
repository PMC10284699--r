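#' Standard Nino index boxes (degrees, longitudes on 0-360)
#'
#' Nino3: 5S-5N, 150W-90W; Nino4: 5S-5N, 160E-150W; Nino3.4: 5S-5N,
#' 170W-120W. The equatorial scan band used to locate the peak anomaly of
#' an event is 2S-2N, 110E-90W.
#' @export
NINO_BOXES <- list(
  nino3  = c(lat_min = -5, lat_max = 5, lon_min = 210, lon_max = 270),
  nino4  = c(lat_min = -5, lat_max = 5, lon_min = 160, lon_max = 210),
  nino34 = c(lat_min = -5, lat_max = 5, lon_min = 190, lon_max = 240),
  scan   = c(lat_min = -2, lat_max = 2, lon_min = 110, lon_max = 270))

# longitude (0-360) of the EP/CP divide, 150 degrees W
EP_CP_DIVIDE_LON <- 210

#' Monthly SST anomalies relative to a climatology window
#'
#' Removes, per cell and per calendar month, the climatological mean over
#' the given window (leave-in convention: the window's own years contribute
#' to the climatology).
#'
#' @param sst a monthly [gridded_field()] of sea surface temperature.
#' @param climatology_window `c(start, end)` years; default the full
#'   record.
#' @return A monthly `gridded_field` of anomalies (K).
#' @export
sst_anomaly <- function(sst, climatology_window = NULL) {
  stopifnot(is_monthly(sst))
  if (is.null(climatology_window))
    climatology_window <- range(sst$years)
  in_win <- sst$years >= climatology_window[1] &
            sst$years <= climatology_window[2]
  if (!any(in_win)) stop("empty climatology window", call. = FALSE)
  if (length(unique(sst$years[in_win])) < 10L)
    warning("climatology window shorter than 10 years")
  d <- dim(sst$values)
  flat <- matrix(sst$values, d[1L], d[2L] * d[3L])
  out <- flat
  for (mo in 1:12) {
    rows <- sst$months == mo
    clim_rows <- rows & in_win
    if (!any(clim_rows)) next
    clim <- colMeans(flat[clim_rows, , drop = FALSE])
    out[rows, ] <- sweep(flat[rows, , drop = FALSE], 2L, clim)
  }
  gridded_field(array(out, d), sst$lat, sst$lon, sst$years, sst$months,
                "K", sst$mask)
}

# DJF (Dec of y-1, Jan and Feb of y) mean anomaly map per labelled year
.djf_mean_maps <- function(anom) {
  yrs <- sort(unique(anom$years))
  d <- dim(anom$values)
  maps <- array(NA_real_, c(length(yrs), d[2L], d[3L]))
  valid <- logical(length(yrs))
  for (k in seq_along(yrs)) {
    y <- yrs[k]
    idx <- which((anom$years == y - 1L & anom$months == 12L) |
                 (anom$years == y & anom$months %in% c(1L, 2L)))
    if (length(idx) == 3L) {
      maps[k, , ] <- colSums(anom$values[idx, , , drop = FALSE],
                             dims = 1L) / 3
      valid[k] <- TRUE
    }
  }
  list(years = yrs, maps = maps, valid = valid)
}

.box_mean <- function(map, lat, lon, box, weighted = TRUE) {
  ii <- lat >= box["lat_min"] & lat <= box["lat_max"]
  jj <- lon >= box["lon_min"] & lon <= box["lon_max"]
  if (!any(ii) || !any(jj)) stop("index box outside the grid", call. = FALSE)
  sub <- map[ii, jj, drop = FALSE]
  w <- if (weighted) matrix(cos_lat_weights(lat[ii]), sum(ii), sum(jj))
       else matrix(1, sum(ii), sum(jj))
  sum(sub * w) / sum(w)
}

#' DJF Nino index from an SST anomaly field
#'
#' Area-weighted box mean of the December(y-1)-February(y) anomaly,
#' labelled year y. The first year, which lacks the preceding December, is
#' flagged invalid.
#'
#' @param anom monthly anomaly [gridded_field()] from [sst_anomaly()].
#' @param box a box name from [NINO_BOXES] (`"nino3"`, `"nino4"`,
#'   `"nino34"`) or a named vector `c(lat_min, lat_max, lon_min, lon_max)`.
#' @return An [annual_series()] of DJF index values (K).
#' @export
nino_index <- function(anom, box = "nino34") {
  if (is.character(box)) box <- NINO_BOXES[[match.arg(box,
                                                      names(NINO_BOXES))]]
  djf <- .djf_mean_maps(anom)
  vals <- vapply(seq_along(djf$years), function(k) {
    if (!djf$valid[k]) return(NA_real_)
    .box_mean(djf$maps[k, , ], anom$lat, anom$lon, box)
  }, numeric(1))
  annual_series(djf$years, vals, "K", djf$valid)
}

#' Classify years as Eastern-Pacific ENSO, Central-Pacific ENSO or neutral
#'
#' A year is an EP ENSO year when the largest DJF SST anomaly over the
#' equatorial band 2S-2N, 110E-90W lies east of 150W and the Nino3 DJF
#' index exceeds 1 standard deviation; a CP ENSO year when the peak lies
#' west of 150W and the Nino4 index exceeds 1 s.d. Standard deviations are
#' computed from the DJF index series over the climatology window.
#' Thresholds are strict (an index exactly at 1 s.d. stays neutral), and a
#' year whose peak side and exceeding index disagree (e.g. peak east of
#' 150W but only Nino4 exceeding) is labelled neutral with a note.
#'
#' @param anom monthly SST anomaly [gridded_field()] (see [sst_anomaly()]).
#' @param climatology_window years over which the index standard deviations
#'   are taken; default the full record.
#' @param detrend detrend the DJF index series linearly before
#'   thresholding (off by default; anomalies are relative to climatology
#'   only).
#' @return An `enso_calendar`: tibble with `year`, `label` (factor
#'   EP/CP/NEUTRAL), `nino3`, `nino4`, `nino34`, `peak_longitude`, `valid`,
#'   `note`, and the threshold s.d. values as attributes `sd_nino3`,
#'   `sd_nino4`.
#' @export
classify_enso_years <- function(anom, climatology_window = NULL,
                                detrend = FALSE) {
  n3 <- nino_index(anom, "nino3")
  n4 <- nino_index(anom, "nino4")
  n34 <- nino_index(anom, "nino34")
  if (detrend) {
    n3 <- detrend_linear(n3); n4 <- detrend_linear(n4)
    n34 <- detrend_linear(n34)
  }
  if (is.null(climatology_window)) climatology_window <- range(anom$years)
  in_win <- function(s) s$valid & s$years >= climatology_window[1] &
                        s$years <= climatology_window[2]
  sd3 <- stats::sd(n3$values[in_win(n3)])
  sd4 <- stats::sd(n4$values[in_win(n4)])
  djf <- .djf_mean_maps(anom)
  ii <- anom$lat >= NINO_BOXES$scan["lat_min"] &
        anom$lat <= NINO_BOXES$scan["lat_max"]
  jj <- anom$lon >= NINO_BOXES$scan["lon_min"] &
        anom$lon <= NINO_BOXES$scan["lon_max"]
  lon_band <- anom$lon[jj]
  peak_lon <- rep(NA_real_, length(djf$years))
  for (k in seq_along(djf$years)) {
    if (!djf$valid[k]) next
    band <- matrix(djf$maps[k, , ], dim(djf$maps)[2L],
                   dim(djf$maps)[3L])[ii, jj, drop = FALSE]
    col_max <- apply(band, 2, max)
    peak_lon[k] <- lon_band[which.max(col_max)]
  }
  label <- rep("NEUTRAL", length(djf$years))
  note <- rep("", length(djf$years))
  for (k in seq_along(djf$years)) {
    if (!djf$valid[k]) next
    east <- peak_lon[k] >= EP_CP_DIVIDE_LON
    if (east && n3$values[k] > sd3) {
      label[k] <- "EP"
    } else if (!east && n4$values[k] > sd4) {
      label[k] <- "CP"
    } else if (east && n4$values[k] > sd4 && n3$values[k] <= sd3) {
      note[k] <- "peak east of 150W but only Nino4 exceeds; kept neutral"
    } else if (!east && n3$values[k] > sd3 && n4$values[k] <= sd4) {
      note[k] <- "peak west of 150W but only Nino3 exceeds; kept neutral"
    }
  }
  out <- tibble::tibble(
    year = djf$years,
    label = factor(label, levels = c("EP", "CP", "NEUTRAL")),
    nino3 = n3$values, nino4 = n4$values, nino34 = n34$values,
    peak_longitude = peak_lon, valid = djf$valid, note = note)
  attr(out, "sd_nino3") <- sd3
  attr(out, "sd_nino4") <- sd4
  class(out) <- c("enso_calendar", class(out))
  out
}
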