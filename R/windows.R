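# one row of the window table
.wstat_row <- function(window, name, bs, p_value, n) {
  tibble::tibble(window_start = window[1], window_end = window[2],
                 statistic = name, estimate = bs$point_estimate,
                 ci_lo = bs$ci[1], ci_hi = bs$ci[2], p_value = p_value,
                 n_years = n, bootstrap = list(bs))
}

# detrend valid years of every series in a bundle restricted to a window
.window_bundle <- function(bundle, window, detrend) {
  sub <- lapply(bundle, window_series, window = window)
  if (detrend == "per_window") sub <- lapply(sub, detrend_linear)
  sub
}

#' Coupling statistics per analysis window
#'
#' Recomputes the full set of water/temperature--CGR coupling statistics
#' within each window: Pearson correlations, temperature- (or water-)
#' controlled partial correlations, the univariate OLS water sensitivity
#' and the bivariate ridge sensitivities, each with case-bootstrap
#' uncertainty. By default every series is re-detrended within each window
#' before statistics are computed; windows may share boundary years.
#'
#' @param bundle named list of [annual_series()] containing at least `cgr`,
#'   `ws` and `temp`; an optional `lagp` series adds the lagged
#'   precipitation variants.
#' @param windows list of `c(start, end)` year pairs.
#' @param n_reps,seed,level bootstrap settings.
#' @param detrend `"per_window"` (default) or `"none"` (use series as
#'   supplied, e.g. already detrended over the full record).
#' @param ridge include the bivariate ridge sensitivities (slower).
#' @param ... passed to [ridge_sensitivity()].
#' @return A tibble with one row per window and statistic: point estimate,
#'   percentile CI, two-sided p-value (t approximation for correlations,
#'   bootstrap sign test for sensitivities), years used, and the
#'   `bootstrap_result` as a list column (for [change_significance()]).
#' @export
window_analysis <- function(bundle, windows, n_reps = 5000, seed = 1,
                            level = 0.95, detrend = c("per_window", "none"),
                            ridge = TRUE, ...) {
  detrend <- match.arg(detrend)
  stopifnot(all(c("cgr", "ws", "temp") %in% names(bundle)))
  span <- range(bundle$cgr$years)
  out <- list()
  for (w in seq_along(windows)) {
    win <- as.numeric(windows[[w]])
    if (win[1] < span[1] || win[2] > span[2])
      stop(sprintf("window %d-%d lies outside the data span %d-%d",
                   win[1], win[2], span[1], span[2]), call. = FALSE)
    sub <- .window_bundle(bundle, win, detrend)
    nv <- length(jointly_valid_years(sub[c("cgr", "ws", "temp")]))
    if (nv < 10L)
      stop(sprintf("window %d-%d has %d valid years; need at least 10",
                   win[1], win[2], nv), call. = FALSE)
    sd0 <- seed + 1000L * w
    rows <- .window_stat_rows(sub, win, n_reps, sd0, level, ridge, ...)
    out[[w]] <- rows
  }
  do.call(rbind, out)
}

.window_stat_rows <- function(sub, win, n_reps, seed, level, ridge, ...) {
  rows <- list()
  add_corr <- function(name, a, b, sd) {
    m <- joint_valid_matrix(list(a = sub[[a]], b = sub[[b]]))
    bs <- bootstrap_stat(function(mm) .corr(mm[, 1], mm[, 2]), m,
                         n_reps, sd, level, name)
    rows[[name]] <<- .wstat_row(win, name, bs,
                                .corr_pvalue(bs$point_estimate, nrow(m)),
                                nrow(m))
  }
  add_partial <- function(name, a, b, ctl, sd) {
    m <- joint_valid_matrix(list(a = sub[[a]], b = sub[[b]],
                                 z = sub[[ctl]]))
    stat <- function(mm) {
      rxy <- .corr(mm[, 1], mm[, 2]); rxz <- .corr(mm[, 1], mm[, 3])
      ryz <- .corr(mm[, 2], mm[, 3])
      if (anyNA(c(rxy, rxz, ryz)) || abs(rxz) >= 1 || abs(ryz) >= 1)
        return(NA_real_)
      .partial_from_corrs(rxy, rxz, ryz)
    }
    bs <- bootstrap_stat(stat, m, n_reps, sd, level, name)
    r <- bs$point_estimate
    t <- r * sqrt((nrow(m) - 3) / max(1 - r^2, .Machine$double.eps))
    rows[[name]] <<- .wstat_row(win, name, bs,
                                2 * stats::pt(-abs(t), df = nrow(m) - 3),
                                nrow(m))
  }
  boot_p <- function(bs) {
    # two-sided bootstrap sign test against zero
    min(1, 2 * min(mean(bs$replicates >= 0), mean(bs$replicates <= 0)))
  }
  waters <- intersect(c("ws", "lagp"), names(sub))
  k <- 0L
  for (wv in waters) {
    k <- k + 100L
    add_corr(paste0("r_", wv, "_cgr"), wv, "cgr", seed + k + 1L)
    add_partial(paste0("r_", wv, "_cgr_given_temp"), wv, "cgr", "temp",
                seed + k + 2L)
    g <- ols_sensitivity(sub$cgr, sub[[wv]], n_reps, seed + k + 3L, level,
                         paste0("gamma_", wv))
    rows[[g$statistic_name]] <- .wstat_row(win, g$statistic_name,
                                           g$bootstrap, boot_p(g$bootstrap),
                                           g$bootstrap$n_reps)
    if (ridge) {
      rp <- ridge_sensitivity(sub$cgr, sub[[wv]], sub$temp, n_reps,
                              seed + k + 4L, level,
                              names = paste0(c(paste0("gamma_", wv),
                                               "gamma_temp"), "_ridge"),
                              ...)
      for (e in list(rp$x1, rp$x2)) {
        nm <- if (e$statistic_name == "gamma_temp_ridge" && wv != "ws")
          paste0(e$statistic_name, "_w", wv) else e$statistic_name
        rows[[nm]] <- .wstat_row(win, nm, e$bootstrap, boot_p(e$bootstrap),
                                 e$bootstrap$n_reps)
      }
    }
  }
  add_corr("r_temp_cgr", "temp", "cgr", seed + 5L)
  add_partial("r_temp_cgr_given_ws", "temp", "cgr", "ws", seed + 6L)
  # n_years for sensitivity rows should report sample years, fix up
  nv <- length(jointly_valid_years(sub[c("cgr", "ws", "temp")]))
  tab <- do.call(rbind, rows)
  tab$n_years <- nv
  tab
}

#' Moving-window coupling statistic
#'
#' Evaluates one coupling statistic in a sliding window of fixed width,
#' indexed by the window's centre year, re-detrending within every window.
#' No bootstrap is attached (use [window_analysis()] on selected windows
#' for uncertainty).
#'
#' @param bundle named list of [annual_series()] with `cgr`, `ws`, `temp`
#'   (and optionally `lagp`).
#' @param width window width in years (default 25; must be at least 5 and
#'   no longer than the record).
#' @param stat one of `"r_ws_cgr"`, `"r_temp_cgr"`,
#'   `"r_ws_cgr_given_temp"`, `"r_temp_cgr_given_ws"`, `"gamma_ws"`,
#'   `"r_lagp_cgr"`, `"gamma_lagp"`.
#' @param detrend `"per_window"` (default) or `"none"`.
#' @param min_valid minimum jointly valid years for a window to be
#'   evaluated (otherwise `NA`).
#' @return Tibble with `centre_year`, `start`, `end`, `value`, `n_years`.
#' @export
moving_window <- function(bundle, width = 25, stat = "r_ws_cgr",
                          detrend = c("per_window", "none"),
                          min_valid = 8) {
  detrend <- match.arg(detrend)
  if (width < 5) stop("window width must be at least 5 years", call. = FALSE)
  yrs <- bundle$cgr$years
  span <- max(yrs) - min(yrs) + 1L
  if (width > span) stop("window width exceeds the record span",
                         call. = FALSE)
  lo <- floor((width - 1) / 2); hi <- width - 1 - lo
  centres <- seq(min(yrs) + lo, max(yrs) - hi)
  rows <- lapply(centres, function(cy) {
    win <- c(cy - lo, cy + hi)
    sub <- tryCatch(.window_bundle(bundle, win, detrend),
                    error = function(e) NULL)
    val <- NA_real_; nv <- 0L
    if (!is.null(sub)) {
      nv <- length(jointly_valid_years(sub[intersect(names(sub),
                                                     c("cgr", "ws", "temp"))]))
      if (nv >= min_valid)
        val <- tryCatch(.point_coupling_stat(stat, sub),
                        error = function(e) NA_real_)
    }
    tibble::tibble(centre_year = cy, start = win[1], end = win[2],
                   value = val, n_years = nv)
  })
  do.call(rbind, rows)
}

.point_coupling_stat <- function(stat, sub) {
  switch(stat,
    r_ws_cgr = pearson_corr(sub$ws, sub$cgr)$r,
    r_temp_cgr = pearson_corr(sub$temp, sub$cgr)$r,
    r_lagp_cgr = pearson_corr(sub$lagp, sub$cgr)$r,
    r_ws_cgr_given_temp = partial_corr(sub$ws, sub$cgr, sub$temp)$r,
    r_temp_cgr_given_ws = partial_corr(sub$temp, sub$cgr, sub$ws)$r,
    gamma_ws = {
      m <- joint_valid_matrix(list(y = sub$cgr, x = sub$ws))
      .slope(m[, 1], m[, 2])
    },
    gamma_lagp = {
      m <- joint_valid_matrix(list(y = sub$cgr, x = sub$lagp))
      .slope(m[, 1], m[, 2])
    },
    stop("unknown statistic: ", stat, call. = FALSE))
}
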