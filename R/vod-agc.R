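#' Four-parameter arctangent mapping from VOD to aboveground carbon
#'
#' `AGC = a * (atan(b*(VOD - c)) - atan(-b*c)) /
#'        (atan(b*(Inf - c)) - atan(-b*c)) + d`
#' with `Inf` a large constant (1e10). For `b > 0` the mapping is monotone
#' non-decreasing and saturates at `a + d` as VOD grows.
#'
#' @param vod numeric vector/matrix of vegetation optical depth.
#' @param a,b,c,d model parameters.
#' @param inf_const saturation constant.
#' @return AGC in the calibration's units (MgC/ha).
#' @export
agc_from_vod <- function(vod, a, b, c, d, inf_const = 1e10) {
  base <- atan(-b * c)
  a * (atan(b * (vod - c)) - base) /
    (atan(b * (inf_const - c)) - base) + d
}

#' Calibrate the VOD to aboveground-carbon mapping
#'
#' Nonlinear least-squares fit of the four-parameter arctangent relation
#' between a VOD map and an aboveground-carbon benchmark map (already in
#' carbon units; see [biomass_to_carbon()] for the biomass conversion).
#' Initialization is multi-start (`b` in 0.5, 1, 5; `a` near the AGC
#' range, `d` near its minimum, `c` near the VOD median) and the best
#' converged start by residual sum of squares is kept.
#'
#' @param vod,agc numeric vectors/matrices/[gridded_field()]s of jointly
#'   observed cells (at least 10 finite pairs).
#' @param inf_const saturation constant of the mapping.
#' @return An `agc_calibration`: parameters `a`, `b`, `c`, `d`,
#'   `inf_const`, the coefficient of determination `fit_r2`, and
#'   `n_cells`.
#' @export
fit_agc_calibration <- function(vod, agc, inf_const = 1e10) {
  if (inherits(vod, "gridded_field")) vod <- vod$values
  if (inherits(agc, "gridded_field")) agc <- agc$values
  vod <- as.numeric(vod); agc <- as.numeric(agc)
  ok <- is.finite(vod) & is.finite(agc)
  vod <- vod[ok]; agc <- agc[ok]
  if (length(vod) < 10)
    stop("need at least 10 jointly valid cells", call. = FALSE)
  tss <- sum((agc - mean(agc))^2)
  if (tss == 0) stop("benchmark AGC has zero variance; fit degenerate",
                     call. = FALSE)
  dat <- data.frame(vod = vod, agc = agc)
  best <- NULL; best_rss <- Inf; diags <- character()
  for (b0 in c(0.5, 1, 5)) {
    start <- list(a = max(diff(range(agc)), 1e-3), b = b0,
                  c = stats::median(vod), d = min(agc))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        agc ~ agc_from_vod(vod, a, b, c, d, inf_const),
        data = dat, start = start,
        lower = c(a = -Inf, b = 1e-8, c = -Inf, d = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) {
        diags <<- c(diags, conditionMessage(e)); NULL
      })
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best))
    stop("calibration fit failed from all starts: ",
         paste(unique(diags), collapse = "; "), call. = FALSE)
  co <- stats::coef(best)
  structure(list(a = co[["a"]], b = co[["b"]], c = co[["c"]],
                 d = co[["d"]], inf_const = inf_const,
                 fit_r2 = 1 - best_rss / tss,
                 n_cells = length(vod)),
            class = "agc_calibration")
}

#' @export
print.agc_calibration <- function(x, ...) {
  cat(sprintf(paste0("<agc_calibration> a = %.4g, b = %.4g, c = %.4g, ",
                     "d = %.4g; R2 = %.3f (n = %d)\n"),
              x$a, x$b, x$c, x$d, x$fit_r2, x$n_cells))
  invisible(x)
}

#' Convert VOD values to aboveground carbon with a calibration
#'
#' Applies the fitted arctangent mapping element-wise. Negative VOD values
#' are masked to `NA` with a warning.
#'
#' @param vod numeric vector/matrix or [gridded_field()].
#' @param cal an `agc_calibration` (or a named list with `a`, `b`, `c`,
#'   `d` and optionally `inf_const`).
#' @return Same shape as `vod`, in MgC/ha.
#' @export
vod_to_agc <- function(vod, cal) {
  inf_const <- if (is.null(cal$inf_const)) 1e10 else cal$inf_const
  apply_fun <- function(v) {
    if (any(v < 0, na.rm = TRUE)) {
      warning("negative VOD values masked to NA")
      v[v < 0] <- NA_real_
    }
    agc_from_vod(v, cal$a, cal$b, cal$c, cal$d, inf_const)
  }
  if (inherits(vod, "gridded_field")) {
    gridded_field(apply_fun(vod$values), vod$lat, vod$lon, vod$years,
                  vod$months, "MgC ha-1", vod$mask)
  } else {
    out <- apply_fun(as.array(vod))
    if (is.null(dim(vod))) as.numeric(out) else out
  }
}

#' Halve biomass density to carbon density
#'
#' Aboveground biomass is conventionally converted to aboveground carbon
#' by a factor of 0.5.
#'
#' @param biomass numeric biomass density values.
#' @param factor carbon fraction of dry biomass.
#' @return Carbon density, same shape.
#' @export
biomass_to_carbon <- function(biomass, factor = 0.5) biomass * factor

#' Semi-arid aboveground-carbon coupling with CGR per window
#'
#' Aggregates AGC over the semi-arid land classes (shrubland and
#' (woody) savanna by default), forms either its year-to-year change (a
#' flux proxy, the default) or its detrended level, and correlates it with
#' CGR within each window after per-window detrending.
#'
#' @param agc yearly (or monthly, averaged) [gridded_field()] of AGC.
#' @param landcover character (or factor) matrix of land-cover classes on
#'   the AGC grid.
#' @param cgr an [annual_series()] of CGR.
#' @param windows list of `c(start, end)` year pairs.
#' @param semiarid_classes classes forming the semi-arid domain.
#' @param mode `"change"` (year-to-year AGC difference) or `"level"`.
#' @param band,weighted aggregation options, see
#'   [area_weighted_tropical_mean()].
#' @return Tibble with one row per window: `window_start`, `window_end`,
#'   `r`, `p`, `n_years`, `mode`.
#' @export
semiarid_agc_cgr_coupling <- function(agc, landcover, cgr, windows,
                                      semiarid_classes = c("shrubland",
                                                           "savanna"),
                                      mode = c("change", "level"),
                                      band = c(-24, 24), weighted = TRUE) {
  mode <- match.arg(mode)
  mask <- matrix(as.character(landcover) %in% semiarid_classes,
                 nrow(landcover), ncol(landcover))
  if (!any(mask)) stop("semi-arid mask is empty", call. = FALSE)
  agg <- area_weighted_tropical_mean(agc, mask = mask, band = band,
                                     mode = "mean", annual = "mean",
                                     weighted = weighted)
  if (mode == "change") {
    vals <- c(NA_real_, diff(agg$values))
    valid <- c(FALSE, agg$valid[-1] & agg$valid[-length(agg$valid)])
    agg <- annual_series(agg$years, vals, paste(agg$units, "yr-1"), valid)
  }
  rows <- lapply(windows, function(win) {
    sub <- .window_bundle(list(agc = agg, cgr = cgr), win, "per_window")
    pc <- pearson_corr(sub$agc, sub$cgr)
    tibble::tibble(window_start = win[1], window_end = win[2], r = pc$r,
                   p = pc$p, n_years = pc$n, mode = mode)
  })
  do.call(rbind, rows)
}
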