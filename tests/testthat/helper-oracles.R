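# Independent oracles used across the suite.

# Exact Mann-Whitney two-sided p by full enumeration of all C(n, n1)
# assignments of the pooled observations to the first sample (tie-free
# inputs only). Independent of the package implementation.
mw_enumeration_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u1_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u1_of(x, y)
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(i) u1_of(pooled[i], pooled[-i]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = min(u_obs, n1 * n2 - u_obs), p = min(p, 1))
}

# Short synthetic series on an exact straight line.
line_series <- function(years = 2000:2009, intercept = 10, slope = -0.5) {
  time_series(years, intercept + slope * (years - years[1]))
}

demo_context <- function() read_context()
demo_registry <- function() read_thresholds()
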