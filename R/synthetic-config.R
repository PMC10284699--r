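#' Default EP/CP ENSO event calendar for synthetic runs
#'
#' A deterministic event schedule loosely patterned on the observed second
#' half of the twentieth century: Eastern-Pacific events concentrated in
#' the earlier decades, Central-Pacific events becoming more frequent in
#' the later ones. Offsets are taken relative to the first year, so any
#' span gets the same shape.
#'
#' @param years integer vector of calendar years.
#' @return Character vector in `{"EP","CP","NEUTRAL"}`, one per year.
#' @export
default_enso_schedule <- function(years) {
  ep_off <- c(6L, 9L, 13L, 17L, 23L, 28L, 38L, 56L)
  cp_off <- c(27L, 31L, 35L, 43L, 45L, 50L, 55L, 58L)
  off <- years - years[1]
  lab <- rep("NEUTRAL", length(years))
  lab[off %in% ep_off] <- "EP"
  lab[off %in% cp_off] <- "CP"
  lab
}

#' Two-era regime-shift ENSO schedule
#'
#' Event calendar for the regime experiment: a neutral first era, in which
#' water anomalies are purely of the spatially compensating kind and the
#' aggregated tropical water signal therefore nearly cancels, followed by
#' a Central-Pacific-enriched second era (ten CP plus two EP events) whose
#' coherent anomalies drive the aggregate. This stylized contrast emulates
#' the observed shift towards more frequent CP events and fewer neutral
#' years.
#'
#' @param years integer vector of calendar years (expected length around
#'   60; the era break is at the midpoint).
#' @return Character vector in `{"EP","CP","NEUTRAL"}`.
#' @export
regime_enso_schedule <- function(years) {
  n <- length(years)
  half <- n %/% 2
  off <- seq_len(n) - 1L
  lab <- rep("NEUTRAL", n)
  era2 <- off[off >= half]
  cp <- era2[seq(1L, length(era2), by = 3L)][1:10]
  ep2 <- setdiff(era2, cp)[c(2L, 12L)]
  lab[off %in% cp] <- "CP"
  lab[off %in% stats::na.omit(ep2)] <- "EP"
  lab
}

# pattern builders -----------------------------------------------------------

# uniform-sign loading pattern, scaled so its area-integrated water mass is
# exactly 1 Tt per unit loading (values in mm)
coherent_pattern_default <- function(lat, lon) {
  nlat <- length(lat); nlon <- length(lon)
  p <- outer(cos(lat * pi / 60), 1 + 0.3 * sin(pi * seq_len(nlon) / nlon))
  p <- 0.5 + p  # strictly positive everywhere
  agg <- sum(p * cell_areas_m2(lat, lon)) / 1e15  # Tt per unit
  p / agg
}

# east-west dipole with exactly zero area-weighted sum, cell scale ~8 mm
dipole_pattern_default <- function(lat, lon) {
  d <- outer(rep(1, length(lat)), sin(2 * pi * (lon - lon[1]) / 360))
  a <- cell_areas_m2(lat, lon)
  d <- d - sum(d * a) / sum(a)
  d * 8 / sqrt(mean(d^2))
}

#' Configuration of the synthetic study generator
#'
#' Collects every knob of the synthetic-data generator with defaults that
#' emulate the observational study conditions: a 59-year record on a
#' tropical grid, ENSO years imposing a spatially coherent water-storage
#' anomaly and neutral years a spatially compensating dipole, tropical
#' temperature tied to ENSO amplitude, and a CGR built linearly from the
#' aggregated water and temperature anomalies plus noise.
#'
#' @param years_start,years_end first and last calendar year.
#' @param grid_shape `c(n_lat, n_lon)` of the tropical land grid spanning
#'   24S-24N.
#' @param gamma_ws water sensitivity of CGR, PgC/yr per Tt H2O.
#' @param gamma_t temperature sensitivity of CGR, PgC/yr per K.
#' @param noise_sd_cgr s.d. of the CGR noise term, PgC/yr.
#' @param enso_schedule per-year labels in `{"EP","CP","NEUTRAL"}`;
#'   default [default_enso_schedule()].
#' @param coherent_pattern uniform-sign `(n_lat, n_lon)` loading (mm per Tt
#'   of aggregate); default scaled so one unit of loading is 1 Tt.
#' @param dipole_pattern spatially compensating loading (area-weighted sum
#'   zero).
#' @param trend_slopes named vector of linear trends per year:
#'   `cgr` (PgC/yr^2), `ws` (mm/yr), `temp` (K/yr), `precip` (mm/mo/yr).
#' @param seed integer RNG seed.
#' @param sst_amplitude ENSO event amplitude as the target DJF Nino box
#'   index, K.
#' @param amp_jitter relative spread of per-event amplitudes.
#' @param w_per_k aggregated water response to ENSO, Tt per K of event
#'   amplitude (events dry the tropics: applied with negative sign).
#' @param t_per_k tropical mean temperature response, K per K.
#' @param loading_noise_sd s.d. of the non-ENSO part of the coherent
#'   loading, Tt.
#' @param neutral_temp_sd s.d. of non-ENSO tropical temperature anomalies,
#'   K.
#' @param ws_cell_noise_sd,temp_cell_noise_sd,precip_cell_noise_sd
#'   independent per-cell noise (mm, K, mm/mo).
#' @param sst_noise_sd per-cell SST noise, K.
#' @param seasonal_amplitude amplitude of the CO2 seasonal cycle, ppm
#'   (default 0 so the annual growth rate inverts the integration exactly).
#' @param pgc_per_ppm CO2 mass conversion, PgC per ppm.
#' @param co2_baseline CO2 concentration anchored at the December before
#'   the first year, ppm.
#' @param cgr_base mean CGR level, PgC/yr.
#' @param precip_base climatological precipitation, mm/month.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(years_start = 1960, years_end = 2018,
                         grid_shape = c(8, 16),
                         gamma_ws = -1.0, gamma_t = 2.0,
                         noise_sd_cgr = 0.5,
                         enso_schedule = NULL,
                         coherent_pattern = NULL, dipole_pattern = NULL,
                         trend_slopes = c(cgr = 0.03, ws = 0, temp = 0.02,
                                          precip = 0),
                         seed = 1,
                         sst_amplitude = 2, amp_jitter = 0.25,
                         w_per_k = 0.8, t_per_k = 0.12,
                         loading_noise_sd = 0.2, neutral_temp_sd = 0.1,
                         ws_cell_noise_sd = 3, temp_cell_noise_sd = 0.1,
                         precip_cell_noise_sd = 5, sst_noise_sd = 0.1,
                         seasonal_amplitude = 0,
                         pgc_per_ppm = PGC_PER_PPM,
                         co2_baseline = 340, cgr_base = 1.5,
                         precip_base = 100) {
  if (years_end <= years_start)
    stop("years_end must exceed years_start", call. = FALSE)
  if (length(grid_shape) != 2L || any(grid_shape < 2))
    stop("grid_shape must be two counts, each at least 2", call. = FALSE)
  years <- seq(years_start, years_end)
  n_lat <- grid_shape[1]; n_lon <- grid_shape[2]
  dl <- 48 / n_lat
  lat <- seq(-24 + dl / 2, 24 - dl / 2, length.out = n_lat)
  dlo <- 360 / n_lon
  lon <- seq(dlo / 2, 360 - dlo / 2, length.out = n_lon)
  if (is.null(enso_schedule)) enso_schedule <- default_enso_schedule(years)
  if (length(enso_schedule) != length(years))
    stop("enso_schedule length must equal the number of years",
         call. = FALSE)
  if (!all(enso_schedule %in% c("EP", "CP", "NEUTRAL")))
    stop("enso_schedule labels must be EP, CP or NEUTRAL", call. = FALSE)
  if (is.null(coherent_pattern))
    coherent_pattern <- coherent_pattern_default(lat, lon)
  if (is.null(dipole_pattern))
    dipole_pattern <- dipole_pattern_default(lat, lon)
  if (!all(dim(coherent_pattern) == grid_shape) ||
      !all(dim(dipole_pattern) == grid_shape))
    stop("pattern dimensions do not match grid_shape", call. = FALSE)
  if (min(coherent_pattern) < 0 && max(coherent_pattern) > 0)
    stop("coherent_pattern entries must all share one sign", call. = FALSE)
  a <- cell_areas_m2(lat, lon)
  if (abs(sum(dipole_pattern * a)) > 0.05 * sum(abs(dipole_pattern) * a))
    stop("dipole_pattern must be spatially compensating ",
         "(area-weighted sum near zero)", call. = FALSE)
  structure(list(
    years = years, years_start = years_start, years_end = years_end,
    grid_shape = grid_shape, lat = lat, lon = lon,
    gamma_ws = gamma_ws, gamma_t = gamma_t, noise_sd_cgr = noise_sd_cgr,
    enso_schedule = enso_schedule, coherent_pattern = coherent_pattern,
    dipole_pattern = dipole_pattern, trend_slopes = trend_slopes,
    seed = as.integer(seed), sst_amplitude = sst_amplitude,
    amp_jitter = amp_jitter, w_per_k = w_per_k, t_per_k = t_per_k,
    loading_noise_sd = loading_noise_sd, neutral_temp_sd = neutral_temp_sd,
    ws_cell_noise_sd = ws_cell_noise_sd,
    temp_cell_noise_sd = temp_cell_noise_sd,
    precip_cell_noise_sd = precip_cell_noise_sd,
    sst_noise_sd = sst_noise_sd,
    seasonal_amplitude = seasonal_amplitude,
    pgc_per_ppm = pgc_per_ppm, co2_baseline = co2_baseline,
    cgr_base = cgr_base, precip_base = precip_base),
    class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("<synth_config> %d-%d, %dx%d grid, gamma_ws = %.3g, ",
                     "gamma_t = %.3g, cgr noise sd = %.3g, seed = %d\n"),
              x$years_start, x$years_end, x$grid_shape[1], x$grid_shape[2],
              x$gamma_ws, x$gamma_t, x$noise_sd_cgr, x$seed))
  tab <- table(factor(x$enso_schedule, c("EP", "CP", "NEUTRAL")))
  cat(sprintf("  schedule: %d EP, %d CP, %d neutral\n",
              tab["EP"], tab["CP"], tab["NEUTRAL"]))
  invisible(x)
}
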