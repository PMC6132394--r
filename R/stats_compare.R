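## Between-site comparison of contaminant levels.

#' Mann-Whitney U test between two sites
#'
#' Rank-sum comparison of two samples of annual pool concentrations. The U
#' statistic is reported as `min(U1, U2)` from midrank-based rank sums. The
#' two-sided p-value is exact (doubled one-tail probability, capped at 1)
#' when the combined sample size is at most 16 and there are no ties;
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param x,y numeric samples (e.g. concentrations from two sites over a
#'   common year range).
#' @return object of class `u_test` with `U`, `p_two_sided`, `method`
#'   (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 + n2 <= 16) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE, conf.int = FALSE)
  )
  u1 <- unname(wt$statistic)        # number of (x_i > y_j) pairs, with midranks
  u <- min(u1, n1 * n2 - u1)
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # fully tied samples: zero variance, no evidence
  structure(list(
    U = u, p_two_sided = min(p, 1),
    method = if (exact) "exact" else "normal_approx",
    n1 = n1, n2 = n2
  ), class = "u_test")
}

#' @export
print.u_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): U = %g, n = (%d, %d), two-sided p = %.4g\n",
              x$method, x$U, x$n1, x$n2, x$p_two_sided))
  invisible(x)
}

#' Restrict two time series to their common year range
#'
#' Helper for unpaired site comparisons over the overlapping monitoring
#' period: returns the values of each series falling within
#' `[max(first years), min(last years)]`.
#'
#' @param a,b [time_series()] objects.
#' @return list with numeric vectors `a` and `b`.
#' @export
common_years <- function(a, b) {
  lo <- max(min(a$years), min(b$years))
  hi <- min(max(a$years), max(b$years))
  list(a = a$values[a$years >= lo & a$years <= hi],
       b = b$values[b$years >= lo & b$years <= hi])
}
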