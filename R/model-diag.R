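#' Bundle of annual series for one model
#'
#' @param model_name text label.
#' @param soil_moisture,nee,temperature [annual_series()] sharing one year
#'   axis (tropical aggregates; NEE is respiration minus photosynthesis,
#'   so a sink is negative).
#' @param soil_moisture_grid optional yearly [gridded_field()] for EOF
#'   analysis.
#' @return An object of class `model_bundle`.
#' @export
model_bundle <- function(model_name, soil_moisture, nee, temperature,
                         soil_moisture_grid = NULL) {
  stopifnot(inherits(soil_moisture, "annual_series"),
            inherits(nee, "annual_series"),
            inherits(temperature, "annual_series"))
  if (!identical(soil_moisture$years, nee$years) ||
      !identical(soil_moisture$years, temperature$years))
    stop("bundle series must share the year axis", call. = FALSE)
  structure(list(model_name = model_name, soil_moisture = soil_moisture,
                 nee = nee, temperature = temperature,
                 soil_moisture_grid = soil_moisture_grid),
            class = "model_bundle")
}

# variable combinations the observational record contributes (carbon flux
# x water proxy), expressed as pseudo model bundles
#' Expand an observational series bundle into flux-by-proxy combinations
#'
#' Given the observational annual series (CGR and optionally the residual
#' land sink as carbon fluxes; water storage and optionally lagged
#' precipitation as water proxies, plus temperature), returns one
#' [model_bundle()] per available flux/proxy combination so the
#' observations can sit alongside model rows in
#' [ensemble_coupling_table()].
#'
#' @param bundle named list of [annual_series()] with `cgr`, `ws`, `temp`
#'   and optionally `rls`, `lagp`.
#' @return List of `model_bundle` objects (up to 4).
#' @export
observation_bundles <- function(bundle) {
  fluxes <- intersect(c("cgr", "rls"), names(bundle))
  waters <- intersect(c("ws", "lagp"), names(bundle))
  out <- list()
  for (fl in fluxes) for (wv in waters) {
    out[[paste(toupper(fl), toupper(wv), sep = "~")]] <-
      model_bundle(paste(toupper(fl), toupper(wv), sep = "~"),
                   soil_moisture = bundle[[wv]], nee = bundle[[fl]],
                   temperature = bundle$temp)
  }
  unname(out)
}

#' Water-carbon coupling metrics across a model ensemble
#'
#' Applies the observational coupling metrics to every model bundle and
#' window: correlation between tropical water (soil moisture) and the
#' carbon flux (NEE), the temperature-controlled partial correlation, and
#' the univariate OLS sensitivity. Series are re-detrended within each
#' window. Windows leaving a model with fewer than 10 jointly valid years
#' are skipped with a warning. Ensemble summary rows report the median,
#' interquartile range and 5th-95th percentiles across models, the
#' statistics a box plot of the ensemble would show.
#'
#' @param bundles list of [model_bundle()] objects.
#' @param windows list of `c(start, end)` year pairs.
#' @param detrend `"per_window"` or `"none"`.
#' @return List with `by_model` (tibble: model, window, statistic, value)
#'   and `summary` (tibble: window, statistic, median, q25, q75, q05,
#'   q95, n_models).
#' @export
ensemble_coupling_table <- function(bundles,
                                    windows = list(c(1960, 1986),
                                                   c(1988, 2014)),
                                    detrend = c("per_window", "none")) {
  detrend <- match.arg(detrend)
  if (length(bundles) < 1) stop("need at least one bundle", call. = FALSE)
  rows <- list()
  for (b in bundles) {
    series <- list(cgr = b$nee, ws = b$soil_moisture, temp = b$temperature)
    for (win in windows) {
      sub <- tryCatch(.window_bundle(series, win, detrend),
                      error = function(e) NULL)
      nv <- if (is.null(sub)) 0L
            else length(jointly_valid_years(sub))
      if (nv < 10L) {
        warning(sprintf("%s: window %d-%d has %d valid years; skipped",
                        b$model_name, win[1], win[2], nv))
        next
      }
      for (st in c("r_ws_cgr", "r_ws_cgr_given_temp", "gamma_ws")) {
        val <- .point_coupling_stat(st, sub)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          model = b$model_name, window_start = win[1], window_end = win[2],
          statistic = sub("ws_cgr", "water_flux", sub("^gamma_ws$",
                                                      "gamma_water", st)),
          value = val, n_years = nv)
      }
    }
  }
  by_model <- do.call(rbind, rows)
  if (is.null(by_model)) stop("no window had enough valid years",
                              call. = FALSE)
  key <- interaction(by_model$window_start, by_model$window_end,
                     by_model$statistic, drop = TRUE)
  summ <- lapply(split(by_model, key), function(d) {
    q <- stats::quantile(d$value, c(0.05, 0.25, 0.5, 0.75, 0.95),
                         type = 7)
    tibble::tibble(window_start = d$window_start[1],
                   window_end = d$window_end[1],
                   statistic = d$statistic[1],
                   median = q[[3]], q25 = q[[2]], q75 = q[[4]],
                   q05 = q[[1]], q95 = q[[5]], n_models = nrow(d))
  })
  list(by_model = by_model, summary = do.call(rbind, unname(summ)))
}

#' Empirical orthogonal function decomposition of a gridded field
#'
#' Singular-value decomposition of the (time x cells) anomaly matrix with
#' sqrt(cos latitude) cell weighting. Patterns are mutually orthogonal
#' under that weighting, explained variance fractions are non-increasing,
#' and each mode's sign is fixed so its largest-magnitude loading is
#' positive. Reconstruction from the full set of modes reproduces the
#' field to numerical tolerance.
#'
#' @param grid yearly anomaly [gridded_field()] (detrended upstream).
#' @param n_modes modes to retain; truncated to the matrix rank with a
#'   warning if larger.
#' @param weighted apply sqrt(cos latitude) weights.
#' @return An `eof_result`: `patterns` (list of lat x lon matrices, `NA`
#'   on masked cells), `pcs` (time x modes matrix), `explained_variance`,
#'   `singular_values`, `years`.
#' @export
eof_decompose <- function(grid, n_modes = 4, weighted = TRUE) {
  stopifnot(inherits(grid, "gridded_field"))
  if (is_monthly(grid)) stop("EOF expects yearly anomalies", call. = FALSE)
  d <- dim(grid$values)
  if (d[1L] < n_modes)
    stop("need at least n_modes time steps", call. = FALSE)
  m <- effective_mask(grid)
  A <- matrix(grid$values, d[1L], d[2L] * d[3L])[, as.vector(m),
                                                 drop = FALSE]
  w <- if (weighted)
    sqrt(matrix(cos_lat_weights(grid$lat), d[2L], d[3L])[m])
  else rep(1, ncol(A))
  Aw <- sweep(A, 2L, w, `*`)
  sv <- svd(Aw)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  if (n_modes > rank) {
    warning(sprintf("requested %d modes but rank is %d; truncated",
                    n_modes, rank))
    n_modes <- rank
  }
  patterns <- vector("list", n_modes)
  pcs <- matrix(NA_real_, d[1L], n_modes)
  for (k in seq_len(n_modes)) {
    v <- sv$v[, k]
    if (v[which.max(abs(v))] < 0) v <- -v
    u <- Aw %*% v  # = u_k * d_k with the same sign fix
    pat <- matrix(NA_real_, d[2L], d[3L])
    pat[m] <- v / w
    patterns[[k]] <- pat
    pcs[, k] <- drop(u)
  }
  structure(list(patterns = patterns, pcs = pcs,
                 explained_variance = sv$d^2 / sum(sv$d^2),
                 singular_values = sv$d, years = grid$years,
                 n_modes = n_modes, weighted = weighted),
            class = "eof_result")
}

#' @export
print.eof_result <- function(x, ...) {
  ev <- x$explained_variance[seq_len(x$n_modes)]
  cat(sprintf("<eof_result> %d modes, explained variance: %s\n",
              x$n_modes, paste(sprintf("%.1f%%", 100 * ev),
                               collapse = ", ")))
  invisible(x)
}
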