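#' Generate a complete synthetic study dataset
#'
#' Produces every input the analysis pipeline consumes, with the
#' statistical structure the analysis assumes. Per year, an ENSO event
#' strength is drawn according to the schedule; ENSO years impose a
#' spatially coherent (uniform-sign) water-storage anomaly whose
#' area-integrated mass is proportional to the event strength, while
#' neutral years impose a spatially compensating dipole; tropical mean
#' temperature anomalies follow the event strength; annual CGR is
#' `cgr_base + trend + gamma_ws * W + gamma_t * T + noise` with `W` the
#' aggregated water anomaly (Tt H2O) and `T` the aggregated temperature
#' anomaly (K); monthly CO2 is the cumulative integral of CGR anchored at
#' December values (plus an optional seasonal cycle); precipitation is laid
#' out so that the July-June lagged sum tracks the water anomaly; SST
#' fields carry the scheduled EP/CP events.
#'
#' The `truth` element records the generating parameters and every
#' realized driver series, sufficient to recompute all series given the
#' seed.
#'
#' @param config a [synth_config()].
#' @return A list of class `study_dataset` with elements `co2_monthly`
#'   (data frame `year`, `month`, `co2_ppm`), `ws`, `precip`, `temp`, `sst`
#'   (monthly [gridded_field()]s), `veg_mask`, `landcover`, `truth` and
#'   `config`.
#' @export
generate_study_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  years <- cf$years
  n <- length(years)
  n_lat <- cf$grid_shape[1]; n_lon <- cf$grid_shape[2]
  n_cell <- n_lat * n_lon
  areas <- cell_areas_m2(cf$lat, cf$lon)
  wmean <- cos_lat_weights(cf$lat)
  wmat <- matrix(wmean, n_lat, n_lon)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cf$seed)

  is_event <- cf$enso_schedule != "NEUTRAL"
  e <- ifelse(is_event,
              cf$sst_amplitude * (1 + cf$amp_jitter * abs(stats::rnorm(n))),
              0)
  loading <- ifelse(is_event,
                    -cf$w_per_k * e +
                      stats::rnorm(n, 0, cf$loading_noise_sd),
                    0)
  dip_loading <- ifelse(is_event, 0, stats::rnorm(n))
  t_anom_mean <- cf$t_per_k * e + stats::rnorm(n, 0, cf$neutral_temp_sd)
  ws_noise <- array(stats::rnorm(n * n_cell, 0, cf$ws_cell_noise_sd),
                    c(n, n_lat, n_lon))
  temp_noise <- array(stats::rnorm(n * n_cell, 0, cf$temp_cell_noise_sd),
                      c(n, n_lat, n_lon))
  cgr_noise <- stats::rnorm(n, 0, cf$noise_sd_cgr)

  # annual anomaly fields
  ws_anom <- array(0, c(n, n_lat, n_lon))
  temp_anom <- array(0, c(n, n_lat, n_lon))
  for (k in seq_len(n)) {
    pat <- if (is_event[k]) loading[k] * cf$coherent_pattern
           else dip_loading[k] * cf$dipole_pattern
    ws_anom[k, , ] <- pat + ws_noise[k, , ]
    temp_anom[k, , ] <- t_anom_mean[k] + temp_noise[k, , ]
  }
  flat_ws <- matrix(ws_anom, n, n_cell)
  ws_anom_tt <- drop(flat_ws %*% as.vector(areas)) / 1e15
  ws_anom_mm <- drop(flat_ws %*% as.vector(wmat)) / sum(wmat)
  flat_t <- matrix(temp_anom, n, n_cell)
  temp_anom_k <- drop(flat_t %*% as.vector(wmat)) / sum(wmat)

  t_off <- years - years[1]
  cgr <- cf$cgr_base + cf$trend_slopes[["cgr"]] * t_off +
    cf$gamma_ws * ws_anom_tt + cf$gamma_t * temp_anom_k + cgr_noise

  # monthly CO2 integrated from CGR, anchored at December values
  inc_ppm <- cgr / cf$pgc_per_ppm
  dec_ppm <- cf$co2_baseline + cumsum(inc_ppm)
  dec_prev <- c(cf$co2_baseline, dec_ppm[-n])
  co2 <- expand.grid(month = 1:12, year = years)[, 2:1]
  co2$co2_ppm <- dec_prev[match(co2$year, years)] +
    (co2$month / 12) * inc_ppm[match(co2$year, years)] +
    cf$seasonal_amplitude * sin(2 * pi * co2$month / 12)

  # monthly gridded fields: yearly values replicated across months
  rep_monthly <- function(annual) {
    out <- array(NA_real_, c(12 * n, n_lat, n_lon))
    for (k in seq_len(n))
      for (mo in 1:12) out[(k - 1) * 12 + mo, , ] <- annual[k, , ]
    out
  }
  m_years <- rep(years, each = 12)
  m_months <- rep(1:12, times = n)
  ws_vals <- rep_monthly(sweep(ws_anom, 1,
                               cf$trend_slopes[["ws"]] * t_off, `+`))
  temp_vals <- rep_monthly(sweep(temp_anom, 1,
                                 298 + cf$trend_slopes[["temp"]] * t_off,
                                 `+`))
  # precipitation: July(y-1)-June(y) window carries year y's water anomaly
  precip_vals <- array(cf$precip_base, c(12 * n, n_lat, n_lon))
  for (k in seq_len(n)) {
    base_k <- cf$precip_base + cf$trend_slopes[["precip"]] * t_off[k]
    for (mo in 1:12) {
      ia <- if (mo <= 6) k else k + 1L  # which LagP year this month feeds
      an <- if (ia <= n) ws_anom_mm[ia] / 12 else 0
      precip_vals[(k - 1) * 12 + mo, , ] <- base_k + an
    }
  }
  precip_vals <- precip_vals +
    array(stats::rnorm(12 * n * n_cell, 0, cf$precip_cell_noise_sd),
          c(12 * n, n_lat, n_lon))

  veg_mask <- matrix(TRUE, n_lat, n_lon)
  landcover <- matrix("forest", n_lat, n_lon)
  lc_idx <- (col(landcover) + row(landcover)) %% 5L
  landcover[lc_idx == 0L] <- "shrubland"
  landcover[lc_idx == 1L] <- "savanna"
  landcover[lc_idx == 2L] <- "grassland"

  sst <- generate_sst_with_enso(cf$enso_schedule,
                                amplitude_sd = cf$sst_amplitude,
                                seed = cf$seed + 101L, years = years,
                                noise_sd = cf$sst_noise_sd,
                                amplitudes = e)

  truth <- list(years = years, schedule = cf$enso_schedule,
                event_strength = e, coherent_loading_tt = loading,
                dipole_loading = dip_loading,
                ws_anom_tt = ws_anom_tt, ws_anom_mm = ws_anom_mm,
                temp_anom_k = temp_anom_k, cgr = cgr, dec_ppm = dec_ppm,
                gamma_ws = cf$gamma_ws, gamma_t = cf$gamma_t,
                noise_sd_cgr = cf$noise_sd_cgr, seed = cf$seed)

  structure(list(
    co2_monthly = co2,
    ws = gridded_field(ws_vals, cf$lat, cf$lon, m_years, m_months,
                       "mm", veg_mask),
    precip = gridded_field(precip_vals, cf$lat, cf$lon, m_years, m_months,
                           "mm month-1", veg_mask),
    temp = gridded_field(temp_vals, cf$lat, cf$lon, m_years, m_months,
                         "K", veg_mask),
    sst = sst, veg_mask = veg_mask, landcover = landcover,
    truth = truth, config = cf),
    class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d-%d, %dx%d land grid, seed %d\n",
              x$config$years_start, x$config$years_end,
              x$config$grid_shape[1], x$config$grid_shape[2],
              x$config$seed))
  invisible(x)
}

#' Generate monthly SST fields with a scripted EP/CP event calendar
#'
#' Builds a 2-degree-latitude tropical Pacific-like SST record in which
#' each scheduled event places a Gaussian warm anomaly in the
#' December-February season: Eastern-Pacific events peak at 120W (east of
#' the 150W divide), Central-Pacific events at 175E (west of it). The
#' anomaly is normalized so the event's DJF Nino3 (EP) or Nino4 (CP) index
#' equals the requested amplitude. Neutral years carry no injected
#' anomaly, so with zero cell noise their indices are exactly zero; with
#' any event present an event index always exceeds one standard deviation
#' of the index series, since that s.d. is at most the amplitude times
#' `sqrt(f(1-f))` for event fraction f. A leading December is generated so
#' the first scheduled year has a complete DJF season.
#'
#' @param schedule character vector of per-year labels in
#'   `{"EP","CP","NEUTRAL"}`.
#' @param amplitude_sd event amplitude: the target DJF Nino box index, K.
#' @param seed integer RNG seed.
#' @param years calendar years (default `1960, 1961, ...`).
#' @param noise_sd independent per-cell, per-month noise, K (default 0).
#' @param amplitudes optional per-year amplitude overrides, K (0 for
#'   neutral years).
#' @return A monthly [gridded_field()] of SST (K).
#' @export
generate_sst_with_enso <- function(schedule, amplitude_sd = 2, seed = 1,
                                   years = NULL, noise_sd = 0,
                                   amplitudes = NULL) {
  if (!all(schedule %in% c("EP", "CP", "NEUTRAL")))
    stop("unknown schedule label", call. = FALSE)
  n <- length(schedule)
  if (is.null(years)) years <- seq(1960, length.out = n)
  if (length(years) != n)
    stop("schedule must cover all years", call. = FALSE)
  lat <- seq(-20, 20, by = 2)
  lon <- seq(2, 358, by = 4)
  n_lat <- length(lat); n_lon <- length(lon)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(amplitudes)) {
    amplitudes <- ifelse(schedule != "NEUTRAL", amplitude_sd, 0)
  }
  if (length(amplitudes) != n)
    stop("amplitudes must cover all years", call. = FALSE)

  blob <- function(centre_lon) {
    outer(exp(-(lat / 6)^2 / 2), exp(-((lon - centre_lon) / 25)^2 / 2))
  }
  norm_blob <- function(centre_lon, box) {
    b <- blob(centre_lon)
    b / .box_mean(b, lat, lon, NINO_BOXES[[box]])
  }
  blob_ep <- norm_blob(240, "nino3")  # 120 W
  blob_cp <- norm_blob(175, "nino4")

  # months: December of years[1]-1, then all months of every year
  m_years <- c(years[1] - 1L, rep(years, each = 12))
  m_months <- c(12L, rep(1:12, times = n))
  n_t <- length(m_years)
  base <- 300 + 1.5 * sin(2 * pi * m_months / 12)
  vals <- array(rep(base, n_lat * n_lon), c(n_t, n_lat, n_lon))
  for (k in seq_len(n)) {
    if (schedule[k] == "NEUTRAL" || amplitudes[k] == 0) next
    pat <- amplitudes[k] * (if (schedule[k] == "EP") blob_ep else blob_cp)
    idx <- which((m_years == years[k] - 1L & m_months == 12L) |
                 (m_years == years[k] & m_months %in% c(1L, 2L)))
    for (i in idx) vals[i, , ] <- vals[i, , ] + pat
  }
  if (noise_sd > 0)
    vals <- vals + array(stats::rnorm(n_t * n_lat * n_lon, 0, noise_sd),
                         c(n_t, n_lat, n_lon))
  gridded_field(vals, lat, lon, m_years, m_months, "K")
}

#' Generate a VOD/AGC calibration pair from the arctangent model
#'
#' Samples vegetation optical depth over a stated positive range and maps
#' it through the four-parameter saturating arctangent relation (plus
#' optional Gaussian noise) to aboveground carbon density.
#'
#' @param params named numeric `c(a, b, c, d)`; `b` must be positive.
#' @param n_cells number of grid cells (at least 10).
#' @param noise_sd Gaussian noise on AGC, MgC/ha.
#' @param seed integer RNG seed.
#' @param vod_range sampling range of VOD values.
#' @return List with `vod`, `agc` (numeric cell vectors) and `params`.
#' @export
generate_vod_agc_pair <- function(params = c(a = 120, b = 3.5, c = 0.45,
                                             d = 5),
                                  n_cells = 500, noise_sd = 0, seed = 1,
                                  vod_range = c(0.05, 1.2)) {
  if (params[["b"]] <= 0) stop("parameter b must be positive",
                               call. = FALSE)
  if (n_cells < 10) stop("need at least 10 cells", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vod <- stats::runif(n_cells, vod_range[1], vod_range[2])
  agc <- agc_from_vod(vod, params[["a"]], params[["b"]], params[["c"]],
                      params[["d"]])
  if (noise_sd > 0) agc <- agc + stats::rnorm(n_cells, 0, noise_sd)
  list(vod = vod, agc = agc, params = params)
}

#' Generate a synthetic model ensemble with fixed water-carbon coupling
#'
#' Each synthetic model supplies tropical soil moisture, global net
#' ecosystem exchange (NEE) and tropical temperature annual series in
#' which the soil-moisture/NEE correlation is set by construction and
#' constant in time, mirroring ensembles whose water-carbon coupling is
#' persistently strong. A target correlation of -1 gives an exactly linear
#' NEE-soil-moisture relation.
#'
#' @param config a [synth_config()] (supplies years and seed).
#' @param n_models number of models (at least 1).
#' @param target_corr per-model soil-moisture/NEE correlation, recycled to
#'   `n_models`; negative values mean wetter years are stronger sinks.
#' @param temp_corr soil-moisture/temperature correlation.
#' @return List of `model_bundle` objects.
#' @export
generate_model_ensemble <- function(config, n_models, target_corr = -0.8,
                                    temp_corr = -0.4) {
  stopifnot(inherits(config, "synth_config"))
  if (n_models < 1) stop("need at least one model", call. = FALSE)
  target_corr <- rep_len(target_corr, n_models)
  years <- config$years
  n <- length(years)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 202L)
  lapply(seq_len(n_models), function(i) {
    rho <- target_corr[i]
    sm <- stats::rnorm(n)
    nee <- rho * sm + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
    tt <- temp_corr * sm + sqrt(max(0, 1 - temp_corr^2)) * stats::rnorm(n)
    model_bundle(sprintf("model_%02d", i),
                 soil_moisture = annual_series(years, sm, "Tt H2O"),
                 nee = annual_series(years, nee, "PgC yr-1"),
                 temperature = annual_series(years, tt, "K"))
  })
}
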