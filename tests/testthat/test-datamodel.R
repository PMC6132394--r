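test_that("CSV records round-trip and validate", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "site,species,tissue,year,analyte,value,unit,basis,censored,water_fraction,lipid_fraction,breathing_water_fraction",
    "NS1,Mytilus edulis,soft body,2016,Pb,0.17,mg/kg,wet,false,0.906,,0.67",
    "NS1,Mytilus edulis,soft body,2015,Pb,0.21,mg/kg,wet,false,0.906,,0.67"
  ), csv)
  rec <- read_samples(csv)
  expect_s3_class(rec, "sample_records")
  expect_equal(nrow(rec), 2)
  expect_equal(rec$value[1], 0.17)
  expect_identical(rec$basis[1], "wet")
  expect_false(rec$censored[1])
  expect_true(is.na(rec$lipid_fraction[1]))

  out <- tempfile(fileext = ".csv")
  write_samples(rec, out)
  rec2 <- read_samples(out)
  expect_equal(rec2, rec)
})

test_that("empty and invalid inputs are handled row by row", {
  csv <- tempfile(fileext = ".csv")
  writeLines("site,species,tissue,year,analyte,value,unit,basis,censored,water_fraction,lipid_fraction,breathing_water_fraction", csv)
  expect_warning(rec <- read_samples(csv), "empty")
  expect_equal(nrow(rec), 0)

  writeLines(c(
    "site,species,tissue,year,analyte,value,unit,basis,censored,water_fraction,lipid_fraction,breathing_water_fraction",
    "NS1,M,soft body,2016,Pb,-1,mg/kg,wet,false,,,"
  ), csv)
  expect_error(read_samples(csv), "row 1.*>= 0")

  writeLines(c(
    "site,species,tissue,year,analyte,value,unit,basis,censored,water_fraction,lipid_fraction,breathing_water_fraction",
    "NS1,M,soft body,2016,Pb,1,stone/acre,wet,false,,,"
  ), csv)
  expect_error(read_samples(csv), "unknown concentration unit")

  writeLines(c(
    "site,species,tissue,year,analyte,value,unit,basis",
    "NS1,M,soft body,2016,Pb,1,mg/kg,wet"
  ), csv)
  expect_error(read_samples(csv), "schema error")

  # duplicate (key, year)
  writeLines(c(
    "site,species,tissue,year,analyte,value,unit,basis,censored,water_fraction,lipid_fraction,breathing_water_fraction",
    "NS1,M,soft body,2016,Pb,1,mg/kg,wet,false,,,",
    "NS1,M,soft body,2016,Pb,2,mg/kg,wet,false,,,"
  ), csv)
  expect_error(read_samples(csv), "duplicate")
})

test_that("records group into sorted, unit-consistent time series", {
  rec <- empty_samples()
  add <- function(rec, site, analyte, year, value, unit = "mg/kg") {
    rbind(rec, data.frame(site = site, species = "M", tissue = "soft body",
                          year = year, analyte = analyte, value = value,
                          unit = unit, basis = "wet", censored = FALSE,
                          water_fraction = NA_real_, lipid_fraction = NA_real_,
                          breathing_water_fraction = NA_real_))
  }
  rec <- add(rec, "NS1", "Pb", 1995L, 0.3)
  rec <- add(rec, "NS1", "Pb", 1993L, 0.4)
  rec <- add(rec, "NS1", "Pb", 2000L, 200, unit = "µg/kg")  # mixed units
  rec <- add(rec, "BS", "Cd", 2000L, 0.1)

  ts <- build_time_series(rec)
  expect_length(ts, 2)
  expect_equal(sum(vapply(ts, length, integer(1))), nrow(rec))
  pb <- ts[[which(vapply(ts, function(s) s$key$analyte, "") == "Pb")]]
  expect_equal(pb$years, c(1993L, 1995L, 2000L))
  # µg/kg record converted into the group's first-seen unit (mg/kg)
  expect_equal(pb$values, c(0.4, 0.3, 0.2))
  expect_identical(pb$key$unit, "mg/kg")
})

test_that("unit conversion steps by factors of 1000 and pg/g equals ng/kg", {
  expect_equal(convert_unit(1, "mg/kg", "µg/kg"), 1000)
  expect_equal(convert_unit(1, "ug/kg", "ng/kg"), 1000)
  expect_equal(convert_unit(5, "pg/g", "ng/kg"), 5)
  expect_equal(convert_unit(convert_unit(3.7, "mg/kg", "pg/g"), "pg/g", "mg/kg"), 3.7)
})

test_that("time series constructor enforces strictly increasing years", {
  expect_error(time_series(c(2000, 2000), c(1, 2)), "duplicate")
  expect_error(time_series(integer(0), numeric(0)), "at least one")
  ts <- time_series(c(2001, 2000), c(2, 1))
  expect_equal(ts$years, c(2000L, 2001L))
  expect_equal(ts$values, c(1, 2))
})
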