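# Shared ordinary-least-squares machinery for the sensitivity and
# attribution estimators. All fits use listwise deletion of missing
# rows, include an intercept, and report two-sided Student's-t
# P-values. The variance inflation factor (VIF) of regressor j is
# 1 / (1 - R^2_j) from the auxiliary regression of j on the remaining
# regressors (plus intercept); it is reported even when the design is
# rank deficient (VIF = Inf for aliased columns), since collinearity
# gating must still be possible there.

regression_result <- function(coefficients, stderr, p_value, r, r2, vif,
                              n, residual_sd, df, ok = TRUE,
                              reason = NA_character_, extra = list()) {
  structure(
    c(list(
      coefficients = coefficients, stderr = stderr, p_value = p_value,
      r = r, r2 = r2, vif = vif, n = n, residual_sd = residual_sd,
      df = df, ok = ok, reason = reason
    ), extra),
    class = "regression_result"
  )
}

missing_result <- function(reason, n = 0L, k = 1L, names = NULL) {
  nm <- c("(Intercept)", names %||% paste0("x", seq_len(k)))
  na <- stats::setNames(rep(NA_real_, k + 1L), nm)
  regression_result(
    coefficients = na, stderr = na, p_value = na, r = NA_real_,
    r2 = NA_real_, vif = stats::setNames(rep(NA_real_, k), nm[-1L]),
    n = n, residual_sd = NA_real_, df = NA_integer_,
    ok = FALSE, reason = reason
  )
}

#' @export
print.regression_result <- function(x, ...) {
  if (!isTRUE(x$ok)) {
    cat(sprintf("<regression_result> missing (%s), n = %d\n", x$reason, x$n))
    return(invisible(x))
  }
  tab <- data.frame(
    estimate = x$coefficients, stderr = x$stderr, p = x$p_value
  )
  cat(sprintf(
    "<regression_result> n = %d, R2 = %.4f, residual sd = %.4g\n",
    x$n, x$r2, x$residual_sd
  ))
  print(tab)
  if (length(x$vif)) {
    cat("VIF:", paste(sprintf("%s = %.3f", names(x$vif), x$vif),
      collapse = ", "
    ), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vif_from_design <- function(X) {
  k <- ncol(X)
  nm <- colnames(X)
  if (k == 1L) {
    return(stats::setNames(1, nm))
  }
  if (k == 2L) {
    # the two auxiliary R^2 are the same squared correlation, so the
    # two VIFs are identical by construction
    s1 <- stats::sd(X[, 1])
    s2 <- stats::sd(X[, 2])
    if (s1 == 0 || s2 == 0) {
      return(stats::setNames(c(Inf, Inf), nm))
    }
    r2 <- stats::cor(X[, 1], X[, 2])^2
    v <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    return(stats::setNames(c(v, v), nm))
  }
  out <- numeric(k)
  for (j in seq_len(k)) {
    xj <- X[, j]
    others <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(others, xj)
    tss <- sum((xj - mean(xj))^2)
    if (tss <= 0) {
      out[j] <- Inf
      next
    }
    rss <- sum(fit$residuals^2)
    r2j <- 1 - rss / tss
    out[j] <- if (r2j >= 1 - 1e-12) Inf else 1 / (1 - r2j)
  }
  stats::setNames(out, nm)
}

# y: response vector; X: regressor matrix (no intercept column), with
# column names. Returns a regression_result.
ols_fit <- function(y, X, min_n = 3L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(y, X)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  n <- length(y)
  k <- ncol(X)
  if (n < max(min_n, k + 2L)) {
    return(missing_result("insufficient_samples", n = n, k = k, names = colnames(X)))
  }
  vif <- vif_from_design(X)
  Xf <- cbind("(Intercept)" = 1, X)
  qx <- qr(Xf)
  if (qx$rank < ncol(Xf)) {
    res <- missing_result("rank_deficient", n = n, k = k, names = colnames(X))
    res$vif <- vif
    return(res)
  }
  fit <- stats::lm.fit(Xf, y)
  beta <- stats::setNames(fit$coefficients, colnames(Xf))
  resid <- fit$residuals
  df <- n - k - 1L
  rss <- sum(resid^2)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(sigma2 * diag(xtx_inv), 0))
  se <- stats::setNames(se, colnames(Xf))
  tval <- beta / se
  p <- stats::setNames(2 * stats::pt(abs(tval), df, lower.tail = FALSE), colnames(Xf))
  # exact fit: a nonzero coefficient with zero stderr is certain
  p[se == 0] <- ifelse(beta[se == 0] != 0, 0, NA_real_)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  r <- NA_real_
  if (k == 1L) {
    sdx <- stats::sd(X[, 1])
    sdy <- stats::sd(y)
    if (sdx > 0 && sdy > 0) {
      r <- stats::cor(X[, 1], y)
    } else {
      r <- 0
    }
    if (sdy == 0) r2 <- 0
  }
  regression_result(
    coefficients = beta, stderr = se, p_value = p, r = r, r2 = r2,
    vif = vif, n = n, residual_sd = sqrt(sigma2), df = df
  )
}
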