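#' @keywords internal
"_PACKAGE"

## Canonical CSV schema for annual pool sample records.
SAMPLE_COLUMNS <- c(
  "site", "species", "tissue", "year", "analyte", "value", "unit", "basis",
  "censored", "water_fraction", "lipid_fraction", "breathing_water_fraction"
)

VALID_UNITS <- c("mg/kg", "µg/kg", "ug/kg", "ng/kg", "pg/g")
VALID_BASES <- c("wet", "dry", "lipid")

## Scale of each unit relative to mg/kg (pg/g is an alias of ng/kg).
.unit_scale <- c("mg/kg" = 1, "µg/kg" = 1e-3, "ng/kg" = 1e-6, "pg/g" = 1e-6)

#' Normalize a concentration unit string
#'
#' Maps ASCII spellings ("ug/kg") onto the canonical set
#' `mg/kg`, `µg/kg`, `ng/kg`, `pg/g`.
#'
#' @param unit character vector of unit strings.
#' @return character vector of canonical unit strings.
#' @export
normalize_unit <- function(unit) {
  u <- trimws(tolower(unit))
  u[u == "ug/kg"] <- "µg/kg"
  bad <- !(u %in% names(.unit_scale)) & !(u == "pg/g")
  if (any(bad)) {
    stop("unknown concentration unit(s): ", paste(unique(unit[bad]), collapse = ", "))
  }
  u
}

#' Convert concentrations between mass-per-mass units
#'
#' Conversion is by factors of 1000 between mg/kg, µg/kg and ng/kg;
#' pg/g is numerically identical to ng/kg.
#'
#' @param value numeric concentrations.
#' @param from,to unit strings (see [normalize_unit()]).
#' @return numeric concentrations expressed in `to`.
#' @export
convert_unit <- function(value, from, to) {
  from <- normalize_unit(from)
  to <- normalize_unit(to)
  unname(value * .unit_scale[from] / .unit_scale[to])
}

#' Validate a data frame of sample records
#'
#' Checks the invariants of an annual pool sample record: non-negative
#' concentration, known unit and basis, fractions within their ranges,
#' integer year, logical censoring flag.
#'
#' @param df data frame with the columns of [read_samples()].
#' @return `df` with normalized units, invisibly; errors mention row numbers.
#' @export
validate_samples <- function(df) {
  missing <- setdiff(SAMPLE_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("schema error: missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    return(invisible(df))
  }
  problems <- character(0)
  note <- function(rows, msg) {
    if (any(rows)) {
      problems <<- c(problems, paste0("row ", which(rows), ": ", msg))
    }
  }
  note(!is.finite(df$value) | df$value < 0, "concentration must be a finite number >= 0")
  note(!(tolower(df$basis) %in% VALID_BASES), "basis must be wet, dry or lipid")
  note(is.na(df$year) | df$year != round(df$year), "year must be an integer")
  note(is.na(df$censored), "censored flag must be TRUE or FALSE")
  frac_bad <- function(x, lo, hi, lo_open = FALSE) {
    !is.na(x) & (x < lo | x >= hi | (lo_open & x <= lo))
  }
  note(frac_bad(df$water_fraction, 0, 1), "water_fraction must lie in [0, 1)")
  note(frac_bad(df$lipid_fraction, 0, 1, lo_open = TRUE), "lipid_fraction must lie in (0, 1)")
  note(frac_bad(df$breathing_water_fraction, 0, 1), "breathing_water_fraction must lie in [0, 1)")
  units_ok <- tryCatch(
    {
      df$unit <- normalize_unit(df$unit)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!units_ok) {
    per_row <- vapply(df$unit, function(u) {
      tryCatch(
        {
          normalize_unit(u)
          TRUE
        },
        error = function(e) FALSE
      )
    }, logical(1))
    note(!per_row, "unknown concentration unit")
    df$unit[per_row] <- normalize_unit(df$unit[per_row])
  }
  if (length(problems) > 0) {
    stop("validation error:\n  ", paste(problems, collapse = "\n  "))
  }
  key <- interaction(df$site, df$species, df$tissue, df$analyte, df$year, drop = TRUE)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop(
      "duplicate error: more than one record for the same sample key and year (rows ",
      paste(dup, collapse = ", "), ")"
    )
  }
  invisible(df)
}

#' Read annual pool sample records from CSV
#'
#' Expects a header row with columns `site, species, tissue, year, analyte,
#' value, unit, basis, censored, water_fraction, lipid_fraction,
#' breathing_water_fraction`. Empty strings denote absent fractions. The
#' `censored` column accepts `true/false` (any case) or `TRUE/FALSE`.
#'
#' @param path path to a UTF-8 CSV file.
#' @return data frame of validated sample records (class `sample_records`).
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                        colClasses = "character", encoding = "UTF-8")
  missing <- setdiff(SAMPLE_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("schema error: missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("empty data section in ", path)
    out <- empty_samples()
    return(out)
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  out <- data.frame(
    site = df$site,
    species = df$species,
    tissue = df$tissue,
    year = num(df$year),
    analyte = df$analyte,
    value = num(df$value),
    unit = df$unit,
    basis = tolower(df$basis),
    censored = tolower(df$censored) %in% c("true", "t", "1", "yes"),
    water_fraction = num(df$water_fraction),
    lipid_fraction = num(df$lipid_fraction),
    breathing_water_fraction = num(df$breathing_water_fraction),
    stringsAsFactors = FALSE
  )
  bad_cens <- !(tolower(df$censored) %in% c("true", "t", "1", "yes", "false", "f", "0", "no"))
  if (any(bad_cens)) {
    stop("validation error:\n  row ", paste(which(bad_cens), collapse = ", row "),
         ": censored flag must be true or false")
  }
  out <- validate_samples(out)
  out$year <- as.integer(out$year)
  class(out) <- c("sample_records", "data.frame")
  out
}

#' An empty, correctly typed sample-record table
#' @return zero-row `sample_records` data frame.
#' @export
empty_samples <- function() {
  out <- data.frame(
    site = character(0), species = character(0), tissue = character(0),
    year = integer(0), analyte = character(0), value = numeric(0),
    unit = character(0), basis = character(0), censored = logical(0),
    water_fraction = numeric(0), lipid_fraction = numeric(0),
    breathing_water_fraction = numeric(0), stringsAsFactors = FALSE
  )
  class(out) <- c("sample_records", "data.frame")
  out
}

#' Write sample records to CSV
#'
#' Inverse of [read_samples()]; `read_samples(write_samples(x, f))` is the
#' identity on validated records.
#'
#' @param records sample-record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(records, path) {
  utils::write.csv(records[, SAMPLE_COLUMNS], path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a contaminant time series
#'
#' @param years integer years, strictly increasing.
#' @param values concentrations (same unit/basis throughout).
#' @param censored logical; TRUE marks values reported at the LOQ.
#' @param key named list identifying the series (site, species, tissue,
#'   analyte, basis, unit).
#' @return object of class `d9_timeseries`.
#' @export
time_series <- function(years, values, censored = rep(FALSE, length(years)),
                        key = list()) {
  if (length(years) < 1) stop("a time series needs at least one point")
  if (length(values) != length(years) || length(censored) != length(years)) {
    stop("years, values and censored must have the same length")
  }
  o <- order(years)
  years <- as.integer(years[o]); values <- values[o]; censored <- censored[o]
  if (any(diff(years) <= 0)) {
    stop("duplicate error: years must be strictly increasing (one point per year)")
  }
  structure(
    list(years = years, values = values, censored = censored, key = key),
    class = "d9_timeseries"
  )
}

#' @export
print.d9_timeseries <- function(x, ...) {
  k <- x$key
  label <- paste(unlist(k[c("site", "species", "tissue", "analyte")]), collapse = " / ")
  cat("Contaminant time series", if (nzchar(label)) paste0("(", label, ")"), "\n")
  cat("  ", length(x$years), " annual pools, ", min(x$years), "-", max(x$years),
      ", ", sum(x$censored), " censored\n", sep = "")
  invisible(x)
}

#' @export
length.d9_timeseries <- function(x) length(x$years)

#' Group sample records into time series
#'
#' Records are grouped by (site, species, tissue, analyte, basis); mixed units
#' within a group are converted to the group's first-seen unit before
#' assembly. Within each group points are sorted by year.
#'
#' @param records validated sample-record data frame.
#' @return list of [time_series()] objects, ordered by group key.
#' @export
build_time_series <- function(records) {
  if (nrow(records) == 0) return(list())
  records <- validate_samples(as.data.frame(records))
  gkey <- paste(records$site, records$species, records$tissue,
                records$analyte, records$basis, sep = "\r")
  groups <- split(seq_len(nrow(records)), gkey)
  groups <- groups[order(names(groups))]
  lapply(groups, function(idx) {
    g <- records[idx[order(records$year[idx])], , drop = FALSE]
    unit0 <- g$unit[1]
    vals <- convert_unit(g$value, g$unit, unit0)
    time_series(
      years = g$year, values = as.numeric(vals), censored = g$censored,
      key = list(site = g$site[1], species = g$species[1], tissue = g$tissue[1],
                 analyte = g$analyte[1], basis = g$basis[1], unit = unit0)
    )
  })
}
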