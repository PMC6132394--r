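ctx <- demo_context()
reg <- demo_registry()

mussel_series <- function(analyte, values, years = 2000:2014, unit = "mg/kg",
                          site = "NS1") {
  time_series(years, values,
              key = list(site = site, species = "Mytilus edulis",
                         tissue = "soft body", analyte = analyte,
                         basis = "wet", unit = unit))
}

test_that("a series far below its maximum level is compliant even after correction", {
  # Pb ML for bivalves is 1.5 mg/kg ww; stay below ML / 3 so the x3
  # breathing-water correction cannot flip the verdict
  s <- mussel_series("Pb", seq(0.4, 0.2, length.out = 15))
  row <- assess_series(s, ctx, reg)
  expect_s3_class(row, "assessment_row")
  statuses <- vapply(row$compliance, function(f) f$status, character(1))
  expect_true(all(statuses == "compliant"))
  expect_equal(round(row$breathing_water_factor), 3)
  # corrected value recorded and never more favourable than uncorrected
  expect_gte(row$corrected_last_measured, row$value_last_measured)
  corr <- vapply(row$compliance, function(f) isTRUE(f$corrected), logical(1))
  expect_true(any(corr))
  for (k in which(corr)) {
    mate <- Filter(function(f) !isTRUE(f$corrected) &&
                     identical(f$value_kind, row$compliance[[k]]$value_kind) &&
                     identical(f$spec$kind, row$compliance[[k]]$spec$kind),
                   row$compliance)
    expect_gte(row$compliance[[k]]$ratio, mate[[1]]$ratio)
  }
})

test_that("early exceedances show up only where corrected values cross the ML", {
  # PAH sum declining from above ML/3 to well below: with the x3 correction
  # only early years exceed the 30 ug/kg ML
  years <- 1990:2005
  vals <- 25 * exp(-0.2 * (years - 1990)) + 1
  s <- mussel_series("Sum4PAH", vals, years, unit = "µg/kg")
  early <- apply_matrix_correction(vals[1], breathing_water_factor(0.67))
  late <- apply_matrix_correction(vals[length(vals)], breathing_water_factor(0.67))
  ml <- lookup_threshold(reg, "Sum4PAH", "bivalve", "ML")
  expect_gt(early / ml$value, 1)
  expect_lt(late / ml$value, 1)
  row <- assess_series(s, ctx, reg)
  # the last-year assessment itself is compliant
  last_flags <- Filter(function(f) identical(f$value_kind, "measured"), row$compliance)
  expect_true(all(vapply(last_flags, function(f) f$status, "") == "compliant"))
})

test_that("diverging calculated and measured last-year values are flagged", {
  vals <- c(seq(4.6, 1.0, length.out = 14), 4.8)
  s <- mussel_series("TBT", vals, 2000:2014, unit = "µg/kg")
  row <- assess_series(s, ctx, reg, divergence_factor = 2)
  expect_true(row$divergence_flag)
  expect_gt(row$divergence_factor, 2)
})

test_that("assessment tables have one deterministic row per series", {
  expect_length(assess_collection(empty_samples(), ctx, reg), 0)

  rec <- do.call(rbind, lapply(c("NS1", "NS2", "BS"), function(site) {
    do.call(rbind, lapply(c("Pb", "Cd"), function(an) {
      simulate_series(series_spec(2000, 2012, 1, c0 = 0.3, decline_rate = 0.02,
                                  noise_cv = 0.2, site = site, analyte = an,
                                  unit = "mg/kg"), seed = 5)$records
    }))
  }))
  tab <- assess_collection(rec, ctx, reg)
  expect_length(tab, 6)
  df <- as.data.frame(tab)
  expect_equal(nrow(df), 6)
  expect_identical(df, as.data.frame(assess_collection(rec, ctx, reg)))
  expect_identical(df$site, sort(df$site))
})

test_that("series too short for any trend become not_assessable rows, not errors", {
  rec <- simulate_series(series_spec(2015, 2016, 1, c0 = 1), seed = 1)$records
  tab <- assess_collection(rec, ctx, reg)
  df <- as.data.frame(tab)
  expect_equal(nrow(df), 1)
  expect_identical(df$worst_status, "not_assessable")
})

test_that("conversion notes allow replaying the corrected value", {
  s <- mussel_series("Pb", seq(0.4, 0.2, length.out = 15))
  row <- assess_series(s, ctx, reg)
  corr <- Filter(function(f) isTRUE(f$corrected), row$compliance)[[1]]
  fac <- as.numeric(sub(".*x([0-9.]+)$", "\\1", corr$basis_note))
  expect_equal(apply_matrix_correction(row$value_last_measured, fac) /
                 corr$threshold_common, corr$ratio, tolerance = 1e-3)
})

test_that("full synthetic campaign assembles the expected assessment pattern", {
  rec <- simulate_demo_campaign(seed = 42)
  tab <- assess_collection(rec, ctx, reg)
  df <- as.data.frame(tab)
  expect_equal(nrow(df), 27)
  # generator ground truth: mussel metals decline and stay below their MLs
  pb <- df[df$analyte == "Pb" & df$species == "Mytilus edulis", ]
  expect_true(all(pb$worst_status == "compliant"))
  expect_true(all(pb$trend == "decreasing"))
  # PBDE is generated orders of magnitude above its 0.0085 ug/kg EQS
  pbde <- df[df$analyte == "PBDE", ]
  expect_true(all(pbde$worst_status == "exceedance"))
})
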