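# Sensitivity estimators: univariate slope of a standardized vegetation
# index on a standardized cloud/climate variable, partial (multiple-
# regression) sensitivities with VIF diagnostics, time-lagged
# sensitivity, and the distributed-lag response profile.

#' Default minimum sample size per temporal resolution
#'
#' 30 paired samples for daily/8-daily series, 12 for monthly — guards
#' against degenerate fits on short overlaps.
#'
#' @param resolution temporal resolution string.
#' @return integer minimum sample size.
#' @export
default_min_n <- function(resolution) {
  switch(resolution,
    "monthly" = 12L,
    "annual" = 12L,
    30L
  )
}

#' Univariate sensitivity (standardized slope)
#'
#' OLS slope `S = dy/dx` with intercept on the listwise-complete pairs;
#' the P-value is a two-sided Student's t test with `n - 2` degrees of
#' freedom. On standardized inputs the slope equals the Pearson
#' correlation.
#'
#' @param y,x numeric series (typically standardized anomalies).
#' @param min_n minimum paired sample size (default 30).
#' @return a `regression_result`; `$ok` is `FALSE` (all estimates `NA`)
#'   when fewer than `min_n` pairs exist or `x` has zero variance.
#' @export
univariate_sensitivity <- function(y, x, min_n = 30L) {
  ols_fit(y, cbind(x = x), min_n = min_n)
}

#' Partial sensitivities from multiple regression
#'
#' Multiple OLS of `y` on the named regressors, with per-coefficient
#' two-sided t P-values (df = n - k - 1) and a variance inflation
#' factor per regressor. With exactly two regressors the result also
#' carries `beta_diff`, the first coefficient minus the second — with
#' precipitation and radiation anomalies as the regressors this is the
#' water-vs-energy balance proxy.
#'
#' @param y response series.
#' @param X named matrix or data.frame of regressors.
#' @param min_n minimum row count after listwise deletion.
#' @return a `regression_result` (with `$vif`; `$ok = FALSE` and a
#'   reason code on rank deficiency).
#' @export
partial_sensitivity <- function(y, X, min_n = 30L) {
  X <- as.matrix(X)
  res <- ols_fit(y, X, min_n = min_n)
  if (isTRUE(res$ok) && ncol(X) == 2L) {
    res$beta_diff <- unname(res$coefficients[2L] - res$coefficients[3L])
  }
  res
}

#' Relative contribution of each regressor coefficient
#'
#' `RC_i = beta_i / sum(beta)`; the contributions sum to 1 by
#' construction and may individually be negative.
#'
#' @param betas named numeric coefficients (intercept excluded).
#' @return named numeric vector summing to 1.
#' @export
relative_contributions <- function(betas) {
  s <- sum(betas)
  if (s == 0) {
    stop("relative contributions are undefined: coefficients sum to zero")
  }
  betas / s
}

#' Time-lagged sensitivity
#'
#' Univariate sensitivity of `y(t)` on `x(t + tau)` over the valid
#' overlap: for `tau > 0` the index range is `1 <= t <= T - tau`, for
#' `tau < 0` it is `1 - tau <= t <= T`. `tau = 0` reproduces
#' [univariate_sensitivity()] exactly (identical sample set).
#'
#' @param y,x numeric series of equal length.
#' @param tau integer lag in periods (negative = `x` leads `y`).
#' @param min_n minimum overlap size.
#' @return a `regression_result`.
#' @export
lagged_sensitivity <- function(y, x, tau, min_n = 30L) {
  stopifnot(length(y) == length(x))
  n <- length(y)
  tau <- as.integer(tau)
  if (abs(tau) >= n) stop("|tau| must be smaller than the series length")
  t_idx <- if (tau >= 0) seq_len(n - tau) else seq.int(1L - tau, n)
  univariate_sensitivity(y[t_idx], x[t_idx + tau], min_n = min_n)
}

#' Distributed-lag response profile
#'
#' Joint multiple OLS of `y(t)` on `x(t + tau)` for
#' `tau = 0, -1, ..., -l`. The effective response period is the lag of
#' the largest coefficient among those significant at `alpha`
#' (two-sided t); ties go to the smaller `|tau|`; the period is
#' undefined (`NA`) when no coefficient is significant. The default
#' `l = 8` corresponds to a maximum lag of 64 days on 8-daily data.
#'
#' @param y,x numeric series of equal length (standardized anomalies).
#' @param l maximum lag in periods (positive integer; lags run 0..-l).
#' @param alpha significance level for the response period (default
#'   0.001).
#' @param min_n minimum fitted rows.
#' @return a `lag_profile`: list with `taus` (0..-l), `betas`,
#'   `p_values`, `effective_response_period`, `n`, `ok`.
#' @export
lag_response_profile <- function(y, x, l = 8L, alpha = 0.001, min_n = 30L) {
  stopifnot(length(y) == length(x), l >= 1L)
  l <- as.integer(l)
  n <- length(y)
  if (n <= l + min_n) stop("series too short for the requested maximum lag")
  t_idx <- seq.int(l + 1L, n)
  X <- vapply(0:l, function(lg) x[t_idx - lg], numeric(length(t_idx)))
  colnames(X) <- sprintf("tau_%d", -(0:l))
  fit <- ols_fit(y[t_idx], X, min_n = min_n)
  taus <- -(0:l)
  if (!isTRUE(fit$ok)) {
    return(structure(
      list(
        taus = taus, betas = rep(NA_real_, l + 1L),
        p_values = rep(NA_real_, l + 1L),
        effective_response_period = NA_integer_,
        alpha = alpha, n = fit$n, ok = FALSE, reason = fit$reason
      ),
      class = "lag_profile"
    ))
  }
  betas <- unname(fit$coefficients[-1L])
  pvals <- unname(fit$p_value[-1L])
  sig <- which(!is.na(pvals) & pvals < alpha)
  eff <- NA_integer_
  if (length(sig)) {
    best <- max(betas[sig])
    cand <- sig[betas[sig] == best] # exact ties -> smaller |tau|
    eff <- taus[cand[which.min(abs(taus[cand]))]]
  }
  structure(
    list(
      taus = taus, betas = betas, p_values = pvals,
      effective_response_period = eff,
      alpha = alpha, n = fit$n, ok = TRUE, reason = NA_character_
    ),
    class = "lag_profile"
  )
}

#' @export
print.lag_profile <- function(x, ...) {
  cat(sprintf(
    "<lag_profile> lags 0..%d, n = %d, effective response period = %s\n",
    min(x$taus), x$n,
    if (is.na(x$effective_response_period)) {
      "undefined"
    } else {
      as.character(x$effective_response_period)
    }
  ))
  invisible(x)
}

#' Pixel-wise sensitivity map
#'
#' Applies [univariate_sensitivity()] (or [lagged_sensitivity()] when
#' `tau != 0`) to every pixel over an optional vegetation mask and
#' collects slope, P-value, correlation and sample-size layers, plus a
#' significance layer at `alpha`.
#'
#' @param y_field,x_field aligned [gridded_field()]s (typically
#'   standardized).
#' @param mask optional logical `lat x lon` matrix; pixels outside the
#'   mask are skipped.
#' @param tau integer lag (periods) applied to `x`, default 0.
#' @param min_n minimum paired samples; defaults per resolution via
#'   [default_min_n()].
#' @param alpha significance level of the `significant` layer
#'   (default 0.001).
#' @return a `sensitivity_map`: list of matrices `S`, `P`, `R`, `N`,
#'   `significant`, plus `lat`/`lon`.
#' @export
sensitivity_map <- function(y_field, x_field, mask = NULL, tau = 0L,
                            min_n = NULL, alpha = 0.001) {
  stopifnot_aligned(y_field, x_field)
  min_n <- min_n %||% default_min_n(y_field$resolution)
  nlat <- length(y_field$lat)
  nlon <- length(y_field$lon)
  S <- P <- R <- matrix(NA_real_, nlat, nlon)
  N <- matrix(NA_integer_, nlat, nlon)
  for (i in seq_len(nlat)) {
    for (j in seq_len(nlon)) {
      if (!is.null(mask) && !isTRUE(mask[i, j])) next
      y <- field_series(y_field, i, j)
      x <- field_series(x_field, i, j)
      res <- if (tau == 0L) {
        univariate_sensitivity(y, x, min_n = min_n)
      } else {
        lagged_sensitivity(y, x, tau, min_n = min_n)
      }
      if (!isTRUE(res$ok)) next
      S[i, j] <- unname(res$coefficients[2L])
      P[i, j] <- unname(res$p_value[2L])
      R[i, j] <- res$r
      N[i, j] <- res$n
    }
  }
  structure(
    list(
      S = S, P = P, R = R, N = N,
      significant = !is.na(P) & P < alpha,
      lat = y_field$lat, lon = y_field$lon,
      alpha = alpha, tau = tau
    ),
    class = "sensitivity_map"
  )
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_map> %d x %d, %d fitted pixels, %d significant (alpha = %g)\n",
    nrow(x$S), ncol(x$S), sum(!is.na(x$S)), sum(x$significant, na.rm = TRUE),
    x$alpha
  ))
  invisible(x)
}

#' Single- vs two-regressor in-sample RMSE comparison
#'
#' Fits the univariate model `y ~ x_single` and the bivariate model
#' `y ~ X_pair` on the identical listwise-complete sample and reports
#' both in-sample RMSEs. Because the models share samples and the
#' two-regressor design nests more information, the univariate RMSE is
#' never larger by construction only when the models are nested in the
#' same regressors; here they differ, so both values are reported for
#' comparison.
#'
#' @param y response series.
#' @param x_single single regressor series.
#' @param X_pair named two-column matrix of regressors.
#' @return list with `rmse_single`, `rmse_pair`, `n`.
#' @export
model_rmse_comparison <- function(y, x_single, X_pair) {
  X_pair <- as.matrix(X_pair)
  keep <- stats::complete.cases(y, x_single, X_pair)
  y <- y[keep]
  x1 <- x_single[keep]
  Xp <- X_pair[keep, , drop = FALSE]
  n <- length(y)
  if (n < 3L) {
    return(list(rmse_single = NA_real_, rmse_pair = NA_real_, n = n))
  }
  f1 <- stats::lm.fit(cbind(1, x1), y)
  f2 <- stats::lm.fit(cbind(1, Xp), y)
  list(
    rmse_single = sqrt(mean(f1$residuals^2)),
    rmse_pair = sqrt(mean(f2$residuals^2)),
    n = n
  )
}

#' Map the RMSE comparison over pixels
#'
#' @param y_field response [gridded_field()].
#' @param x_field single-regressor field (e.g. CF anomalies).
#' @param pair_fields list of exactly two aligned fields (e.g.
#'   precipitation and radiation anomalies).
#' @param mask optional logical pixel mask.
#' @return list of matrices `rmse_single`, `rmse_pair` and their
#'   pixel-wise Pearson `correlation`.
#' @export
rmse_comparison_map <- function(y_field, x_field, pair_fields, mask = NULL) {
  stopifnot(length(pair_fields) == 2L)
  stopifnot_aligned(y_field, x_field)
  for (f in pair_fields) stopifnot_aligned(y_field, f)
  nlat <- length(y_field$lat)
  nlon <- length(y_field$lon)
  r1 <- r2m <- matrix(NA_real_, nlat, nlon)
  for (i in seq_len(nlat)) {
    for (j in seq_len(nlon)) {
      if (!is.null(mask) && !isTRUE(mask[i, j])) next
      cmp <- model_rmse_comparison(
        field_series(y_field, i, j),
        field_series(x_field, i, j),
        cbind(
          a = field_series(pair_fields[[1]], i, j),
          b = field_series(pair_fields[[2]], i, j)
        )
      )
      r1[i, j] <- cmp$rmse_single
      r2m[i, j] <- cmp$rmse_pair
    }
  }
  ok <- !is.na(r1) & !is.na(r2m)
  list(
    rmse_single = r1, rmse_pair = r2m,
    correlation = if (sum(ok) > 2) stats::cor(r1[ok], r2m[ok]) else NA_real_
  )
}
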