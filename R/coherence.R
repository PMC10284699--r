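# anomaly matrix (time x active cells) and optional per-cell weights
.coh_matrix <- function(anom, weighted) {
  stopifnot(inherits(anom, "gridded_field"))
  if (is_monthly(anom)) stop("coherence expects yearly anomaly maps",
                             call. = FALSE)
  d <- dim(anom$values)
  m <- effective_mask(anom)
  A <- matrix(anom$values, d[1L], d[2L] * d[3L])[, as.vector(m),
                                                 drop = FALSE]
  w <- if (weighted) {
    matrix(cos_lat_weights(anom$lat), d[2L], d[3L])[m]
  } else rep(1, ncol(A))
  list(A = A, w = w, years = anom$years)
}

#' Spatial coherence of gridded anomalies over a period
#'
#' Builds the temporal covariance between every pair of distinct grid
#' cells over the window and reports the percentage ratio of the signed to
#' the absolute pairwise covariance sums:
#' `100 * (tcov+ + tcov-) / tcov`, with `tcov = sum_{i != j} |c_ij|`.
#' 100 means every cell co-varies with one sign; values near or below zero
#' mean positive covariances are counterbalanced by negative ones
#' (spatially compensating anomalies). The cell-pair matrix is accumulated
#' in column blocks so it is never materialized at once.
#'
#' @param anom yearly anomaly [gridded_field()] (detrended upstream).
#' @param window optional `c(start, end)` years; default the full record.
#' @param weighted multiply each pair by the product of cos-latitude
#'   weights (off by default).
#' @param block_size number of cell columns per block.
#' @return Coherence percentage in `[-100, 100]`.
#' @export
period_coherence <- function(anom, window = NULL, weighted = FALSE,
                             block_size = 512L) {
  cm <- .coh_matrix(anom, weighted)
  keep <- if (is.null(window)) rep(TRUE, length(cm$years))
          else cm$years >= window[1] & cm$years <= window[2]
  if (sum(keep) < 3L) stop("need at least 3 years in the window",
                           call. = FALSE)
  A <- cm$A[keep, , drop = FALSE]
  if (ncol(A) < 2L) stop("need at least 2 unmasked cells", call. = FALSE)
  A <- sweep(A, 2L, colMeans(A))
  A <- sweep(A, 2L, cm$w, `*`)
  n <- nrow(A)
  abs_sum <- 0; signed_sum <- 0; diag_sum <- 0
  for (j0 in seq(1L, ncol(A), by = block_size)) {
    j1 <- min(j0 + block_size - 1L, ncol(A))
    cb <- crossprod(A, A[, j0:j1, drop = FALSE]) / (n - 1)
    abs_sum <- abs_sum + sum(abs(cb))
    signed_sum <- signed_sum + sum(cb)
    diag_sum <- diag_sum + sum(diag(cb[j0:j1, , drop = FALSE]))
  }
  abs_sum <- abs_sum - diag_sum      # variances are positive, drop both
  signed_sum <- signed_sum - diag_sum
  if (abs_sum <= 0) stop("all pairwise covariances are zero", call. = FALSE)
  # ratio before scaling keeps the +/-100 bounds exactly attainable;
  # clamp absorbs summation-order rounding at the boundary
  100 * max(-1, min(1, signed_sum / abs_sum))
}

#' Year-by-year spatial coherence with tercile bins
#'
#' Restricts the pairwise-covariance coherence to a single year's
#' contribution: with `x_i` the anomaly of cell i in year t,
#' `coherence(t) = 100 * ((sum x)^2 - sum x^2) / ((sum |x|)^2 - sum x^2)`,
#' i.e. the signed over absolute sums of the off-diagonal outer-product
#' terms. Valid years are binned into LOW / MEDIUM / HIGH terciles at the
#' 33.3rd and 66.6th percentiles of the coherence values.
#'
#' @param anom yearly anomaly [gridded_field()].
#' @param weighted weight cell pairs by products of cos-latitude weights.
#' @param bin_window optional `c(start, end)` years over which the tercile
#'   break points are computed (default: all valid years jointly).
#' @return A `coherence_series`: tibble with `year`, `coherence` (percent),
#'   `bin` (ordered factor LOW/MEDIUM/HIGH) and `valid`. Years with fewer
#'   than two nonzero cell anomalies are flagged invalid.
#' @export
yearly_coherence <- function(anom, weighted = FALSE, bin_window = NULL) {
  cm <- .coh_matrix(anom, weighted)
  A <- sweep(cm$A, 2L, cm$w, `*`)
  s1 <- rowSums(A)
  s2 <- rowSums(A^2)
  sa <- rowSums(abs(A))
  denom <- sa^2 - s2
  nonzero <- rowSums(A != 0)
  valid <- nonzero >= 2L & denom > 0
  coh <- ifelse(valid,
                100 * pmax(-1, pmin(1, (s1^2 - s2) / denom)),
                NA_real_)
  bin_years <- if (is.null(bin_window)) valid
               else valid & cm$years >= bin_window[1] &
                    cm$years <= bin_window[2]
  q <- stats::quantile(coh[bin_years], c(1 / 3, 2 / 3), na.rm = TRUE)
  # manual interval assignment: duplicate break points (ties, constant
  # coherence) must not error
  lab <- ifelse(coh <= q[1], "LOW", ifelse(coh <= q[2], "MEDIUM", "HIGH"))
  bin <- factor(lab, levels = c("LOW", "MEDIUM", "HIGH"),
                ordered = TRUE)
  out <- tibble::tibble(year = cm$years, coherence = coh, bin = bin,
                        valid = valid)
  attr(out, "tercile_breaks") <- unname(q)
  class(out) <- c("coherence_series", class(out))
  out
}

#' Fraction of high-coherence years in a window
#'
#' @param cs a `coherence_series` from [yearly_coherence()] (bins assigned
#'   over the full record so windows are comparable).
#' @param window `c(start, end)` years, inclusive.
#' @return Fraction of valid in-window years whose bin is HIGH.
#' @export
coherence_fraction <- function(cs, window) {
  keep <- cs$valid & cs$year >= window[1] & cs$year <= window[2]
  if (!any(keep)) stop("no valid years inside the window", call. = FALSE)
  mean(cs$bin[keep] == "HIGH")
}

#' Water--CGR coupling conditioned on spatial coherence level
#'
#' Splits the valid years by coherence tercile and computes, within each
#' bin, the correlation between tropical water storage and CGR and the
#' temperature-controlled partial correlation. Bins with fewer than
#' `min_years` usable years are reported as undefined rather than raising.
#'
#' @param cs a `coherence_series`.
#' @param cgr,ws,temp detrended [annual_series()].
#' @param min_years minimum years per bin.
#' @return Tibble with one row per bin: `bin`, `n`, `r_ws_cgr`, `p`,
#'   `r_ws_cgr_given_temp`, `p_partial`, `defined`.
#' @export
subset_coupling <- function(cs, cgr, ws, temp, min_years = 5) {
  rows <- lapply(c("LOW", "MEDIUM", "HIGH"), function(b) {
    yrs_bin <- cs$year[cs$valid & cs$bin == b]
    sub <- lapply(list(cgr = cgr, ws = ws, temp = temp), function(s) {
      annual_series(s$years, s$values, s$units,
                    s$valid & s$years %in% yrs_bin)
    })
    n <- length(jointly_valid_years(sub))
    res <- tibble::tibble(bin = b, n = n, r_ws_cgr = NA_real_,
                          p = NA_real_, r_ws_cgr_given_temp = NA_real_,
                          p_partial = NA_real_, defined = FALSE)
    if (n >= max(min_years, 4L)) {
      ok <- tryCatch({
        pc <- pearson_corr(sub$ws, sub$cgr)
        pp <- partial_corr(sub$ws, sub$cgr, sub$temp)
        res$r_ws_cgr <- pc$r; res$p <- pc$p
        res$r_ws_cgr_given_temp <- pp$r; res$p_partial <- pp$p
        res$defined <- TRUE
        TRUE
      }, error = function(e) FALSE)
      if (!ok) res$defined <- FALSE
    }
    res
  })
  do.call(rbind, rows)
}
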