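test_that("the local linear smoother reproduces straight lines and constants", {
  ts <- line_series(2000:2009, 10, -0.5)
  f <- loess_fit(ts)
  expect_equal(f$fitted, ts$values, tolerance = 1e-10)
  expect_equal(f$rss, 0, tolerance = 1e-18)

  cts <- time_series(2000:2009, rep(3.3, 10))
  fc <- loess_fit(cts)
  expect_equal(fc$fitted, rep(3.3, 10), tolerance = 1e-12)
  expect_equal(fc$sigma2, 0, tolerance = 1e-20)
})

test_that("full-span uniform-weight smoother equals the OLS line", {
  set.seed(42)
  yr <- 2000:2009
  y <- 5 - 0.1 * (yr - 2000) + rnorm(10, 0, 0.3)
  f <- loess_fit(time_series(yr, y), window_years = 1000, weights = "uniform")
  ols <- unname(stats::fitted(stats::lm(y ~ yr)))
  expect_equal(f$fitted, ols, tolerance = 1e-8)
  expect_equal(f$trace, 2, tolerance = 1e-10)
})

test_that("hat rows sum to one and the smoother commutes with constant shifts", {
  set.seed(7)
  yr <- seq(2001, 2021, by = 2)  # gappy biennial series
  y <- rlnorm(length(yr))
  f <- loess_fit(time_series(yr, y))
  expect_equal(unname(rowSums(f$hat)), rep(1, length(yr)), tolerance = 1e-10)
  f2 <- loess_fit(time_series(yr, y + 100))
  expect_equal(f2$fitted, f$fitted + 100, tolerance = 1e-8)
})

test_that("smoother preconditions and censoring substitution are honoured", {
  expect_error(loess_fit(time_series(2000:2003, 1:4)), "at least 5")
  ts <- time_series(2000:2009, rep(2, 10), censored = c(rep(TRUE, 5), rep(FALSE, 5)))
  f_up <- loess_fit(ts)                                # LOQ (upper bound)
  f_half <- loess_fit(ts, censored_substitution = "half")
  expect_equal(f_up$y, rep(2, 10))
  expect_equal(f_half$y, c(rep(1, 5), rep(2, 5)))
})

test_that("log-scale fitting linearizes exponential declines", {
  yr <- 2000:2011
  vals <- 8 * exp(-0.3 * (yr - 2000))          # exact exponential
  f <- loess_fit(time_series(yr, vals), log_scale = TRUE)
  expect_equal(f$fitted, log(vals), tolerance = 1e-9)
  expect_equal(f$rss, 0, tolerance = 1e-16)
  expect_error(loess_fit(time_series(yr, vals - 1), log_scale = TRUE),
               "positive")
})

test_that("trend ANOVA detects declines, ignores noise, and flags humps", {
  dec <- simulate_series(series_spec(2000, 2014, 1, c0 = 10, decline_rate = 0.1,
                                     noise_cv = 0.05), seed = 7)
  a <- trend_anova(dec$series)
  expect_lt(a$p_linear, 0.001)
  expect_identical(a$overall_trend, "decreasing")
  expect_lt(a$slope, 0)

  # symmetric hump: rise then fall, no net slope
  hump <- simulate_series(series_spec(2000, 2019, 1, c0 = 1, decline_rate = 0,
                                      nonlinear_amplitude = 2, noise_cv = 0.02),
                          seed = 3)
  h <- trend_anova(hump$series)
  expect_gt(h$p_linear, 0.05)
  expect_lt(h$p_nonlinear, 0.05)
  expect_identical(h$overall_trend, "none")

  expect_error(trend_anova(time_series(2000:2005, 1:6)), "at least 7")
})

test_that("contrast test enforces the 7-year span and is symmetric in its endpoints", {
  dec <- simulate_series(series_spec(1998, 2017, 1, c0 = 10, decline_rate = 0.08,
                                     noise_cv = 0.1), seed = 5)
  f <- loess_fit(dec$series)
  expect_error(contrast_test(f, 2010, 2016), "at least 7 years")

  ct <- contrast_test(f, 1998, 2017)
  expect_lt(ct$p, 0.05)
  expect_lt(ct$difference, 0)
  ct_rev <- contrast_test(f, 2017, 1998)
  expect_equal(ct_rev$p, ct$p)
  expect_equal(ct_rev$difference, -ct$difference)
  expect_error(contrast_test(f, 1990, 2017), "fitted years")
})

test_that("linear trend endpoints, percent change and divergence factors", {
  # exact line through (2000,10) ... (2010,0)
  ts <- time_series(c(2000, 2005, 2010), c(10, 5, 0))
  lt <- linear_trend(ts)
  expect_equal(lt$slope, -1, tolerance = 1e-12)
  expect_equal(lt$calc_last, 0, tolerance = 1e-9)
  expect_equal(lt$percent_change, -100, tolerance = 1e-6)
  expect_identical(lt$last_year_status, "value")

  # steep decline whose OLS line crosses zero before the final year
  ts2 <- time_series(2000:2006, c(30, 20, 10, 2, 0.5, 0.2, 0.1))
  lt2 <- linear_trend(ts2)
  expect_lt(lt2$calc_last, 0)
  expect_identical(lt2$last_year_status, "not_detected")
  expect_true(is.na(lt2$percent_change))
  expect_true(is.na(lt2$calc_vs_measured_factor))

  # calculated vs measured divergence factor is max/min
  ts3 <- time_series(2000:2009, c(seq(4.6, 1.0, length.out = 9), 3.6))
  lt3 <- linear_trend(ts3)
  expect_equal(lt3$calc_vs_measured_factor,
               max(lt3$calc_last, 3.6) / min(lt3$calc_last, 3.6))
  expect_error(linear_trend(time_series(2000:2001, 1:2)), "at least 3")
})

test_that("null series reject at roughly the nominal rate", {
  # small Monte-Carlo version of the calibration check (the full-size run
  # lives in the acceptance suite)
  set.seed(2024)
  seeds <- sample.int(2^30, 400)
  rej <- mean(vapply(seeds, function(s) {
    ss <- simulate_series(series_spec(2000, 2014, 1, c0 = 5, decline_rate = 0,
                                      noise_cv = 0.2), seed = s)
    trend_anova(ss$series)$p_linear <= 0.05
  }, logical(1)))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("OLS slope CI covers the generator tangent slope in most replicates", {
  set.seed(99)
  seeds <- sample.int(2^30, 200)
  k <- 0.02
  covered <- vapply(seeds, function(s) {
    sim <- simulate_series(series_spec(2000, 2019, 1, c0 = 10, decline_rate = k,
                                       noise_cv = 0.05), seed = s)
    yr <- as.numeric(sim$series$years)
    m <- stats::lm(sim$series$values ~ yr)
    ci <- stats::confint(m, "yr", level = 0.95)
    # generator tangent at the series midpoint
    tmid <- mean(yr) - yr[1]
    tangent <- -k * 10 * exp(-k * tmid)
    ci[1] <= tangent && tangent <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
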