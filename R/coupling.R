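# fast product-moment helpers on plain vectors -------------------------------

.corr <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

.corr_pvalue <- function(r, n) {
  if (!is.finite(r) || n < 3L) return(NA_real_)
  r <- min(max(r, -1), 1)
  if (abs(r) == 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

.partial_from_corrs <- function(rxy, rxz, ryz) {
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

.slope <- function(y, x) {
  vx <- stats::var(x)
  if (vx == 0) return(NA_real_)
  stats::cov(x, y) / vx
}

#' Pearson correlation between two annual series
#'
#' Product-moment correlation over the jointly valid years, with a
#' two-sided p-value from the t approximation. Both series are expected to
#' be detrended upstream.
#'
#' @param x,y [annual_series()] objects (or numeric vectors of equal
#'   length).
#' @return List with elements `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (inherits(x, "annual_series")) {
    m <- joint_valid_matrix(list(x = x, y = y))
    x <- m[, 1]; y <- m[, 2]
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 jointly valid years", call. = FALSE)
  r <- .corr(x, y)
  if (!is.finite(r))
    stop("zero variance in one of the series", call. = FALSE)
  list(r = r, p = .corr_pvalue(r, n), n = n)
}

#' Partial correlation controlling a third variable
#'
#' Correlation between `x` and `y` after linearly removing `z` from both;
#' computed from the three pairwise correlations,
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' which equals the correlation of the OLS residuals of `x` on `z` and of
#' `y` on `z`.
#'
#' @param x,y,z [annual_series()] objects or numeric vectors.
#' @return List with elements `r`, `p`, `n` (p from the t approximation
#'   with `n - 3` degrees of freedom).
#' @export
partial_corr <- function(x, y, z) {
  if (inherits(x, "annual_series")) {
    m <- joint_valid_matrix(list(x = x, y = y, z = z))
    x <- m[, 1]; y <- m[, 2]; z <- m[, 3]
  }
  n <- length(x)
  if (n < 4L) stop("need at least 4 jointly valid years", call. = FALSE)
  rxy <- .corr(x, y); rxz <- .corr(x, z); ryz <- .corr(y, z)
  if (anyNA(c(rxy, rxz, ryz)))
    stop("zero variance in one of the series", call. = FALSE)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    # a variable fully explained by the control leaves no residual signal;
    # 0/0 with a vanishing numerator is resolved to zero, anything else is
    # genuine collinearity
    if (abs(rxy - rxz * ryz) < 1e-10)
      return(list(r = 0, p = 1, n = n))
    stop("control variable collinear with x or y", call. = FALSE)
  }
  r <- .partial_from_corrs(rxy, rxz, ryz)
  if (!is.finite(r)) r <- 0
  t <- r * sqrt((n - 3) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 3), n = n)
}

# bootstrap ------------------------------------------------------------------

new_bootstrap_result <- function(statistic_name, replicates, point_estimate,
                                 level, seed) {
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(replicates, c(alpha, 1 - alpha), type = 7))
  structure(list(statistic_name = statistic_name, replicates = replicates,
                 point_estimate = point_estimate, ci = ci, level = level,
                 n_reps = length(replicates), seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s = %.4g, %d%% CI [%.4g, %.4g], %d reps\n",
              x$statistic_name, x$point_estimate, round(100 * x$level),
              x$ci[1], x$ci[2], x$n_reps))
  invisible(x)
}

#' Case (pairs) bootstrap of a statistic over annual series
#'
#' Resamples years jointly across all supplied series with replacement, so
#' cross-variable dependence is preserved, and returns the replicate
#' distribution with a percentile confidence interval. Replicates on which
#' the statistic is degenerate (non-finite) are redrawn, up to ten times
#' the requested replicate count in total draws.
#'
#' @param stat function taking a numeric matrix (columns = series, rows =
#'   resampled years) and returning a scalar.
#' @param data named list of [annual_series()] (jointly valid years are
#'   used) or a numeric matrix.
#' @param n_reps number of bootstrap replicates.
#' @param seed integer RNG seed.
#' @param level confidence level of the percentile interval.
#' @param statistic_name label stored in the result.
#' @return A `bootstrap_result`.
#' @export
bootstrap_stat <- function(stat, data, n_reps = 5000, seed = 1,
                           level = 0.95, statistic_name = "statistic") {
  m <- if (is.matrix(m0 <- data)) m0 else joint_valid_matrix(data)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 jointly valid years", call. = FALSE)
  point <- stat(m)
  if (!is.finite(point))
    stop("statistic degenerate on the full sample", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  reps <- numeric(n_reps)
  got <- 0L; draws <- 0L; cap <- 10L * n_reps
  while (got < n_reps) {
    if (draws >= cap)
      stop("bootstrap redraw cap exceeded (degenerate replicates)",
           call. = FALSE)
    draws <- draws + 1L
    idx <- sample.int(n, n, replace = TRUE)
    v <- stat(m[idx, , drop = FALSE])
    if (is.finite(v)) {
      got <- got + 1L
      reps[got] <- v
    }
  }
  new_bootstrap_result(statistic_name, reps, point, level, seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Significance of a change between two bootstrap distributions
#'
#' Pairs the replicates of two independently resampled bootstrap results
#' and evaluates how consistently their difference keeps one sign:
#' `p = 2 * min(Pr(D >= 0), Pr(D <= 0))`, capped at 1, with
#' `D = b_replicate - a_replicate`.
#'
#' @param a,b `bootstrap_result` objects for the same statistic computed on
#'   two periods (independent resampling).
#' @return List with `delta` (point estimate difference `b - a`) and `p`.
#' @export
change_significance <- function(a, b) {
  stopifnot(inherits(a, "bootstrap_result"), inherits(b, "bootstrap_result"))
  if (!identical(a$statistic_name, b$statistic_name))
    stop("bootstrap results refer to different statistics", call. = FALSE)
  k <- min(a$n_reps, b$n_reps)
  d <- b$replicates[seq_len(k)] - a$replicates[seq_len(k)]
  p <- 2 * min(mean(d >= 0), mean(d <= 0))
  list(delta = b$point_estimate - a$point_estimate, p = min(p, 1))
}

# sensitivities --------------------------------------------------------------

new_sensitivity_estimate <- function(gamma, model_kind, regularization,
                                     bootstrap, name) {
  structure(list(gamma = gamma, model_kind = model_kind,
                 regularization = regularization, bootstrap = bootstrap,
                 statistic_name = name),
            class = "sensitivity_estimate")
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat(sprintf("<sensitivity_estimate> %s (%s): gamma = %.4g", x$statistic_name,
              x$model_kind, x$gamma))
  if (!is.null(x$bootstrap))
    cat(sprintf(", %d%% CI [%.4g, %.4g]", round(100 * x$bootstrap$level),
                x$bootstrap$ci[1], x$bootstrap$ci[2]))
  cat("\n")
  invisible(x)
}

#' Univariate interannual sensitivity (OLS slope)
#'
#' Slope of the OLS regression of `y` on `x` over jointly valid years, with
#' case-bootstrap uncertainty. Both variables are expected to be detrended
#' upstream; units follow the inputs (e.g. PgC/yr per Tt H2O).
#'
#' @param y,x [annual_series()] objects (response, predictor).
#' @param n_reps,seed,level bootstrap settings, see [bootstrap_stat()].
#' @param name label for the estimate.
#' @return A `sensitivity_estimate` with `model_kind = "univariate_ols"`.
#' @export
ols_sensitivity <- function(y, x, n_reps = 5000, seed = 1, level = 0.95,
                            name = "gamma") {
  m <- joint_valid_matrix(list(y = y, x = x))
  if (nrow(m) < 3L) stop("need at least 3 jointly valid years", call. = FALSE)
  if (stats::var(m[, 2]) == 0)
    stop("zero predictor variance", call. = FALSE)
  stat <- function(mm) .slope(mm[, 1], mm[, 2])
  bs <- bootstrap_stat(stat, m, n_reps, seed, level, name)
  new_sensitivity_estimate(bs$point_estimate, "univariate_ols", 0, bs, name)
}

# closed-form ridge for two standardized predictors, vectorized over lambda
.ridge2 <- function(s11, s22, s12, b1, b2, lambda) {
  A <- s11 + lambda; B <- s22 + lambda
  det <- A * B - s12^2
  list(beta1 = (B * b1 - s12 * b2) / det,
       beta2 = (A * b2 - s12 * b1) / det)
}

.standardize <- function(x) {
  mu <- mean(x); sd <- stats::sd(x)
  list(z = if (sd > 0) (x - mu) / sd else x * 0, mu = mu, sd = sd)
}

# one ridge fit on raw vectors at fixed lambda; returns slopes in raw units
.ridge_fit_raw <- function(y, x1, x2, lambda) {
  s1 <- .standardize(x1); s2 <- .standardize(x2)
  if (s1$sd == 0 || s2$sd == 0) return(c(NA_real_, NA_real_))
  yc <- y - mean(y)
  s11 <- sum(s1$z^2); s22 <- sum(s2$z^2); s12 <- sum(s1$z * s2$z)
  b1 <- sum(s1$z * yc); b2 <- sum(s2$z * yc)
  if ((s11 + lambda) * (s22 + lambda) - s12^2 <= 0) return(c(NA_real_, NA_real_))
  co <- .ridge2(s11, s22, s12, b1, b2, lambda)
  c(co$beta1 / s1$sd, co$beta2 / s2$sd)
}

#' Choose the ridge penalty by repeated random-split validation
#'
#' The sample is split `n_splits` times into training and validation sets;
#' for every split the validation mean squared error is evaluated on a grid
#' of penalties spaced evenly on a log scale, the best penalty per split is
#' recorded, and the average of the winners is returned.
#'
#' @param y,x1,x2 numeric vectors (response and two predictors).
#' @param lambda_grid penalty grid, default 100 values in `[1e-4, 1e2]`.
#' @param n_splits number of random splits.
#' @param val_frac fraction held out per split.
#' @param seed integer RNG seed.
#' @return List with `lambda` (the averaged winner) and `winners` per split.
#' @export
select_ridge_lambda <- function(y, x1, x2,
                                lambda_grid = 10^seq(-4, 2, length.out = 100),
                                n_splits = 25, val_frac = 0.25, seed = 1) {
  n <- length(y)
  n_val <- max(2L, floor(n * val_frac))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  winners <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    val <- sample.int(n, n_val)
    tr <- setdiff(seq_len(n), val)
    z1 <- .standardize(x1[tr]); z2 <- .standardize(x2[tr])
    if (z1$sd == 0 || z2$sd == 0) { winners[s] <- min(lambda_grid); next }
    yc <- y[tr] - mean(y[tr])
    s11 <- sum(z1$z^2); s22 <- sum(z2$z^2); s12 <- sum(z1$z * z2$z)
    b1 <- sum(z1$z * yc); b2 <- sum(z2$z * yc)
    co <- .ridge2(s11, s22, s12, b1, b2, lambda_grid)
    v1 <- (x1[val] - z1$mu) / z1$sd
    v2 <- (x2[val] - z2$mu) / z2$sd
    pred <- mean(y[tr]) + outer(v1, co$beta1) + outer(v2, co$beta2)
    mse <- colMeans((y[val] - pred)^2)
    winners[s] <- lambda_grid[which.min(mse)]
  }
  list(lambda = mean(winners), winners = winners)
}

#' Bivariate interannual sensitivities via ridge regression
#'
#' Regresses `y` on two (typically collinear) predictors with a quadratic
#' coefficient penalty. Predictors are standardized, the penalty is chosen
#' by [select_ridge_lambda()] (25 random splits, 100 log-spaced values,
#' average of the per-split winners) unless supplied, coefficients are
#' rescaled to the original units, and uncertainty comes from a case
#' bootstrap at the fixed selected penalty. `mode = "ols"` forces a zero
#' penalty (plain bivariate OLS) and errors on perfectly collinear
#' predictors, which the ridge mode tolerates with a warning.
#'
#' @param y,x1,x2 [annual_series()] objects.
#' @param n_reps,seed,level bootstrap settings.
#' @param lambda fixed penalty; `NULL` (default) selects it by validation.
#' @param lambda_grid,n_splits,val_frac passed to [select_ridge_lambda()].
#' @param mode `"ridge"` or `"ols"`.
#' @param names labels for the two coefficient estimates.
#' @return List of class `sensitivity_pair`: two `sensitivity_estimate`s
#'   (`x1`, `x2`) plus the penalty used (`lambda`).
#' @export
ridge_sensitivity <- function(y, x1, x2, n_reps = 5000, seed = 1,
                              level = 0.95, lambda = NULL,
                              lambda_grid = 10^seq(-4, 2, length.out = 100),
                              n_splits = 25, val_frac = 0.25,
                              mode = c("ridge", "ols"),
                              names = c("gamma_x1", "gamma_x2")) {
  mode <- match.arg(mode)
  m <- joint_valid_matrix(list(y = y, x1 = x1, x2 = x2))
  n <- nrow(m)
  if (n < 6L) stop("need at least 6 jointly valid years", call. = FALSE)
  r12 <- .corr(m[, 2], m[, 3])
  if (!is.finite(r12) || abs(r12) >= 1 - 1e-12) {
    if (mode == "ols")
      stop("predictors perfectly collinear; OLS mode undefined",
           call. = FALSE)
    warning("predictors (near-)perfectly collinear; ridge estimates shared")
  }
  if (mode == "ols") {
    lambda <- 0
  } else if (is.null(lambda)) {
    lambda <- select_ridge_lambda(m[, 1], m[, 2], m[, 3], lambda_grid,
                                  n_splits, val_frac, seed)$lambda
  }
  point <- .ridge_fit_raw(m[, 1], m[, 2], m[, 3], lambda)
  if (anyNA(point)) stop("degenerate design (zero predictor variance)",
                         call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  reps <- matrix(NA_real_, n_reps, 2L)
  got <- 0L; draws <- 0L; cap <- 10L * n_reps
  while (got < n_reps) {
    if (draws >= cap)
      stop("bootstrap redraw cap exceeded (degenerate replicates)",
           call. = FALSE)
    draws <- draws + 1L
    idx <- sample.int(n, n, replace = TRUE)
    co <- .ridge_fit_raw(m[idx, 1], m[idx, 2], m[idx, 3], lambda)
    if (all(is.finite(co))) {
      got <- got + 1L
      reps[got, ] <- co
    }
  }
  kind <- if (mode == "ols") "bivariate_ols" else "bivariate_ridge"
  est <- lapply(1:2, function(j)
    new_sensitivity_estimate(point[j], kind, lambda,
                             new_bootstrap_result(names[j], reps[, j],
                                                  point[j], level, seed + 1L),
                             names[j]))
  structure(list(x1 = est[[1]], x2 = est[[2]], lambda = lambda,
                 collinearity = r12),
            class = "sensitivity_pair")
}
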