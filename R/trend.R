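## Temporal trend machinery for annual contaminant series: a fixed-window
## local linear smoother with explicit hat rows, ANOVA decomposition of the
## trend into linear and non-linear components, and a contrast test between
## fitted values at two time points. The hat rows make the smoother a linear
## operator, which is what the variance calculations of the ANOVA and the
## contrast test rely on.

.tricube <- function(u) {
  w <- (1 - pmin(abs(u), 1)^3)^3
  w[abs(u) >= 1] <- 0
  w
}

## Hat row of the local linear fit at target year t: fitted(t) = l' y with
## l = e1' (X'WX)^{-1} X'W, X = [1, year - t]. Returns a length-n vector.
.local_hat_row <- function(years, t, halfwidth, weights = c("tricube", "uniform")) {
  weights <- match.arg(weights)
  d <- abs(years - t)
  idx <- which(d <= halfwidth + 1e-9)
  h <- halfwidth
  if (length(idx) < 3) {
    ## too few points in the fixed window: widen symmetrically to the
    ## nearest 3 points and rescale the kernel so all of them carry weight
    idx <- order(d)[seq_len(min(3, length(years)))]
    h <- max(d[idx]) * (1 + 1e-6)
    if (h == 0) h <- 1
  }
  w <- if (weights == "uniform") rep(1, length(idx)) else .tricube(d[idx] / h)
  if (sum(w > 0) < 2) {
    ## degenerate kernel (e.g. equidistant flanking points exactly at the
    ## boundary): fall back to positive weights on the included points
    h <- max(d[idx]) * (1 + 1e-6)
    w <- if (weights == "uniform") rep(1, length(idx)) else .tricube(d[idx] / h)
  }
  x <- years[idx] - t
  X <- cbind(1, x)
  XtW <- t(X * w)
  M <- XtW %*% X
  l <- rep(0, length(years))
  l[idx] <- as.numeric(solve(M, XtW)[1, ])
  l
}

#' Fixed-window LOESS smoother for an annual series
#'
#' Fits a locally weighted linear regression at each observation year, using
#' tricube weights over a fixed window of `window_years` (so points within
#' `window_years / 2` of the target year contribute). Windows holding fewer
#' than 3 points are widened symmetrically to the nearest 3 points. The fit
#' at each year is a linear combination of the observations; these hat rows
#' are stored and drive all downstream inference.
#'
#' Censored observations enter at their reported LOQ by default
#' (`censored_substitution = "loq"`, the upper-bound convention) or at half
#' of it (`"half"`).
#'
#' @param series a [time_series()].
#' @param window_years window width in years (default 7).
#' @param weights local weight kernel; `"uniform"` turns each local fit into
#'   an unweighted regression (with a full-span window this reproduces the
#'   ordinary least-squares line).
#' @param censored_substitution substitution rule for censored points.
#' @param log_scale fit on the log-concentration scale (all values must be
#'   positive); the default is the raw scale, which allows the trend line
#'   to extrapolate below zero ("not detected") as assessment tables expect.
#' @return object of class `smoother_fit` with elements `years`, `y`
#'   (observations used, on the fitting scale), `fitted`, `hat` (n x n
#'   matrix of hat rows), `trace` (model degrees of freedom, tr(H)),
#'   `residual_df` (n - tr(H)), `rss`, `sigma2`, `window_years`.
#' @export
loess_fit <- function(series, window_years = 7,
                      weights = c("tricube", "uniform"),
                      censored_substitution = c("loq", "half"),
                      log_scale = FALSE) {
  weights <- match.arg(weights)
  censored_substitution <- match.arg(censored_substitution)
  if (window_years <= 0) stop("window_years must be > 0")
  n <- length(series$years)
  if (n < 5) stop("insufficient data: the smoother needs at least 5 annual pools")
  y <- series$values
  if (censored_substitution == "half") {
    y <- ifelse(series$censored, y / 2, y)
  }
  if (log_scale) {
    if (any(y <= 0)) stop("log-scale fitting requires strictly positive values")
    y <- log(y)
  }
  years <- as.numeric(series$years)
  H <- t(vapply(years, function(t) {
    .local_hat_row(years, t, window_years / 2, weights)
  }, numeric(n)))
  fitted <- as.numeric(H %*% y)
  rss <- sum((y - fitted)^2)
  tr <- sum(diag(H))
  residual_df <- n - tr
  structure(list(
    years = series$years, y = y, fitted = fitted, hat = H,
    trace = tr, residual_df = residual_df, rss = rss,
    sigma2 = if (residual_df > 0) rss / residual_df else NA_real_,
    window_years = window_years, weights = weights, log_scale = log_scale,
    key = series$key
  ), class = "smoother_fit")
}

#' @export
print.smoother_fit <- function(x, ...) {
  cat("Local linear smoother (window ", x$window_years, " years)\n", sep = "")
  cat(sprintf("  n = %d, model df = %.2f, residual df = %.2f, sigma2 = %.4g\n",
              length(x$years), x$trace, x$residual_df, x$sigma2))
  invisible(x)
}

#' ANOVA decomposition of a temporal trend
#'
#' Tests the linear and non-linear components of a trend by comparing three
#' nested fits: the overall mean, the ordinary least-squares line, and the
#' fixed-window smoother of [loess_fit()]. With residual sums of squares
#' RSS0, RSS1, RSS2 and smoother degrees of freedom df2 = tr(H),
#' \deqn{F_{lin} = \frac{(RSS_0 - RSS_1)/1}{RSS_2 / (n - df_2)}, \qquad
#'       F_{nonlin} = \frac{(RSS_1 - RSS_2)/(df_2 - 2)}{RSS_2 / (n - df_2)}}
#' with p-values from the corresponding F distributions (degrees of freedom
#' may be non-integer; the first-order trace approximation is used for the
#' smoother df — a two-trace correction tr(2H - HH') would be slightly more
#' conservative and is not applied).
#'
#' @param series a [time_series()] with at least 7 points.
#' @param window_years smoother window in years.
#' @param alpha significance level used to label the overall trend.
#' @param ... passed to [loess_fit()].
#' @return object of class `trend_test` with `F_linear`, `p_linear`,
#'   `F_nonlinear`, `p_nonlinear` (NA when the smoother is no rougher than a
#'   line), `slope` (OLS), `overall_trend` in
#'   `c("decreasing", "increasing", "none")`, `significant`, and the
#'   component fits.
#' @export
trend_anova <- function(series, window_years = 7, alpha = 0.05, ...) {
  n <- length(series$years)
  if (n < 7) stop("insufficient data: trend ANOVA needs at least 7 annual pools")
  sm <- loess_fit(series, window_years = window_years, ...)
  y <- sm$y
  years <- as.numeric(series$years)
  rss0 <- sum((y - mean(y))^2)
  m1 <- stats::lm(y ~ years)
  rss1 <- sum(stats::residuals(m1)^2)
  rss2 <- sm$rss
  df2 <- sm$trace
  dfres <- n - df2
  if (dfres <= 0) stop("smoother leaves no residual degrees of freedom")
  ms_res <- rss2 / dfres
  if (ms_res <= 0) {
    ## perfect smoother fit: any explained variation is infinitely significant
    F_lin <- if (rss0 > rss1) Inf else 0
    p_lin <- if (rss0 > rss1) 0 else 1
  } else {
    F_lin <- (rss0 - rss1) / ms_res
    p_lin <- stats::pf(F_lin, 1, dfres, lower.tail = FALSE)
  }
  if (df2 > 2 + 1e-8) {
    if (ms_res <= 0) {
      F_nonlin <- if (rss1 > rss2) Inf else 0
      p_nonlin <- if (rss1 > rss2) 0 else 1
    } else {
      F_nonlin <- ((rss1 - rss2) / (df2 - 2)) / ms_res
      p_nonlin <- stats::pf(F_nonlin, df2 - 2, dfres, lower.tail = FALSE)
    }
  } else {
    F_nonlin <- NA_real_
    p_nonlin <- NA_real_
  }
  slope <- unname(stats::coef(m1)[2])
  significant <- is.finite(p_lin) && p_lin <= alpha
  structure(list(
    F_linear = F_lin, p_linear = p_lin,
    F_nonlinear = F_nonlin, p_nonlinear = p_nonlin,
    slope = slope, alpha = alpha,
    overall_trend = if (significant) {
      if (slope < 0) "decreasing" else "increasing"
    } else "none",
    significant = significant,
    rss = c(mean = rss0, linear = rss1, smoother = rss2),
    df_smoother = df2, df_residual = dfres,
    smoother = sm, n = n
  ), class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("Trend ANOVA (n = %d)\n", x$n))
  cat(sprintf("  linear component:     F = %.3g, p = %.4g\n", x$F_linear, x$p_linear))
  if (is.na(x$p_nonlinear)) {
    cat("  non-linear component: not applicable (smoother df <= 2)\n")
  } else {
    cat(sprintf("  non-linear component: F = %.3g, p = %.4g\n",
                x$F_nonlinear, x$p_nonlinear))
  }
  cat("  overall trend:", x$overall_trend,
      if (x$significant) sprintf("(significant at alpha = %g)", x$alpha) else "", "\n")
  invisible(x)
}

#' Contrast test between two fitted time points
#'
#' Tests whether the smoothed concentration differs between two years at
#' least 7 years apart. Because the smoother is linear in the observations,
#' the difference of fitted values has variance
#' `sigma2 * ||l_b - l_a||^2` where `l_a`, `l_b` are the hat rows; the test
#' statistic is referred to a t distribution on the smoother's residual
#' degrees of freedom.
#'
#' @param fit a [loess_fit()] result.
#' @param year_a,year_b years to compare; both must be fitted years and span
#'   at least `min_span` years.
#' @param min_span minimum span in years required for the contrast
#'   (default 7; shorter spans are refused).
#' @return list with `difference` (fitted(year_b) - fitted(year_a)), `se`,
#'   `t`, `p` (two-sided), `df`.
#' @export
contrast_test <- function(fit, year_a, year_b, min_span = 7) {
  if (abs(year_b - year_a) < min_span) {
    stop("contrast test requires a time span of at least ", min_span, " years")
  }
  ia <- match(year_a, fit$years)
  ib <- match(year_b, fit$years)
  if (is.na(ia) || is.na(ib)) {
    stop("both contrast years must be fitted years of the series")
  }
  diff <- fit$fitted[ib] - fit$fitted[ia]
  l <- fit$hat[ib, ] - fit$hat[ia, ]
  se <- sqrt(fit$sigma2 * sum(l^2))
  if (!is.finite(se) || se == 0) {
    tstat <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    tstat <- diff / se
    p <- 2 * stats::pt(-abs(tstat), df = fit$residual_df)
  }
  list(difference = diff, se = se, t = tstat, p = p, df = fit$residual_df,
       year_a = year_a, year_b = year_b)
}

#' Linear trend line and last-year endpoints
#'
#' Ordinary least-squares regression of concentration on year, on the raw
#' concentration scale. The trend-line value in the final sampling year
#' (`calc_last`) is reported alongside the measured value; a negative
#' `calc_last` is interpreted as "not detected" and the percent change is
#' then not applicable. When both the calculated and measured last-year
#' values are positive, their ratio (larger over smaller) flags series where
#' the trend line does not adequately reflect the final year.
#'
#' @param series a [time_series()] with at least 3 points.
#' @param censored_substitution substitution rule for censored points
#'   (`"loq"` upper bound, default, or `"half"`).
#' @return object of class `linear_trend` with `slope`, `intercept`,
#'   `slope_p`, `calc_first`, `calc_last`, `percent_change`,
#'   `last_year_status` (`"value"` or `"not_detected"`), `measured_last`,
#'   `calc_vs_measured_factor`.
#' @export
linear_trend <- function(series, censored_substitution = c("loq", "half")) {
  censored_substitution <- match.arg(censored_substitution)
  n <- length(series$years)
  if (n < 3) stop("insufficient data: linear trend needs at least 3 annual pools")
  y <- series$values
  if (censored_substitution == "half") y <- ifelse(series$censored, y / 2, y)
  years <- as.numeric(series$years)
  m <- stats::lm(y ~ years)
  cf <- stats::coef(m)
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  calc_first <- intercept + slope * years[1]
  calc_last <- intercept + slope * years[n]
  measured_last <- y[n]
  not_detected <- calc_last < 0
  sm <- summary(m)
  slope_p <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
  structure(list(
    slope = slope, intercept = intercept, slope_p = slope_p,
    calc_first = calc_first, calc_last = calc_last,
    percent_change = if (not_detected || calc_first == 0) NA_real_ else
      100 * (calc_last - calc_first) / calc_first,
    last_year_status = if (not_detected) "not_detected" else "value",
    measured_last = measured_last,
    calc_vs_measured_factor = if (!not_detected && calc_last > 0 && measured_last > 0)
      max(calc_last, measured_last) / min(calc_last, measured_last) else NA_real_,
    year_first = series$years[1], year_last = series$years[n], n = n
  ), class = "linear_trend")
}

#' @export
print.linear_trend <- function(x, ...) {
  cat(sprintf("Linear trend %d-%d (n = %d): slope %.4g per year\n",
              x$year_first, x$year_last, x$n, x$slope))
  if (x$last_year_status == "not_detected") {
    cat("  trend-line value in final year < 0: not detected\n")
  } else {
    cat(sprintf("  final year: calculated %.4g, measured %.4g (factor %.2g), change %+.1f%%\n",
                x$calc_last, x$measured_last, x$calc_vs_measured_factor,
                x$percent_change))
  }
  invisible(x)
}
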