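## Assessment engine: per site x species x tissue x analyte series it
## summarizes the monitoring period, runs the trend machinery, evaluates
## last-year values (measured and trend-line calculated, uncorrected and
## breathing-water corrected) against every applicable threshold, and flags
## series where the trend line diverges from the final measurement.

#' Load a site/matrix context table
#'
#' Context files are JSON with a `sites` mapping (site id to
#' `water_fraction` and `breathing_water_fraction`) and a `matrix_classes`
#' mapping from `"species/tissue"` to a threshold matrix class.
#'
#' @param path context JSON path; default is the bundled demo context.
#' @return list with `sites` and `matrix_classes`.
#' @export
read_context <- function(path = system.file("extdata", "sites_demo.json",
                                            package = "d9assess")) {
  if (!file.exists(path)) stop("context file not found: ", path)
  raw <- jsonlite::fromJSON(path)
  if (is.null(raw$sites)) stop("context file must contain a 'sites' mapping")
  list(sites = raw$sites,
       matrix_classes = if (is.null(raw$matrix_classes)) list() else raw$matrix_classes)
}

## Breathing-water correction applies to mussel soft-body samples with a
## known breathing-water fraction; other matrices are reported uncorrected.
.bw_fraction <- function(series, context) {
  if (!identical(series$key$tissue, "soft body")) return(NA_real_)
  site <- series$key$site
  b <- context$sites[[site]]$breathing_water_fraction
  if (is.null(b) || is.na(b)) NA_real_ else as.numeric(b)
}

.matrix_class <- function(series, context) {
  key <- paste(series$key$species, series$key$tissue, sep = "/")
  mc <- context$matrix_classes[[key]]
  if (is.null(mc)) NA_character_ else mc
}

#' Assess one contaminant time series
#'
#' Runs the linear trend (always) and the trend ANOVA (when at least 7
#' pools are available), then checks both the measured and the trend-line
#' calculated last-year concentration against every applicable threshold —
#' uncorrected and, for mussel soft-body series with a known
#' breathing-water fraction, corrected for breathing-water dilution. Series
#' where calculated and measured last-year values differ by at least
#' `divergence_factor` are flagged, signalling that the trend line may not
#' adequately reflect the final year.
#'
#' @param series a [time_series()].
#' @param context a [read_context()] list.
#' @param registry a [read_thresholds()] registry.
#' @param alpha significance level for the trend label.
#' @param window_years smoother window.
#' @param divergence_factor flag threshold for calculated-vs-measured ratio.
#' @return list of class `assessment_row`.
#' @export
assess_series <- function(series, context, registry, alpha = 0.05,
                          window_years = 7, divergence_factor = 2) {
  key <- series$key
  n <- length(series$years)
  lin <- linear_trend(series)
  tr <- if (n >= 7) {
    tryCatch(trend_anova(series, window_years = window_years, alpha = alpha),
             error = function(e) NULL)
  } else NULL
  b <- .bw_fraction(series, context)
  bw_factor <- if (is.na(b)) NA_real_ else breathing_water_factor(b)
  mc <- .matrix_class(series, context)
  site_ctx <- context$sites[[key$site]]
  basis_ctx <- list(water_fraction = if (is.null(site_ctx)) NA_real_ else
    as.numeric(site_ctx$water_fraction))
  measured_last <- lin$measured_last
  calc_last <- if (lin$last_year_status == "value") lin$calc_last else NA_real_
  notes <- character(0)
  compliance <- list()
  if (!is.na(mc)) {
    specs <- applicable_thresholds(registry, key$analyte, mc)
    for (j in seq_len(nrow(specs))) {
      spec <- as.list(specs[j, , drop = FALSE])
      candidates <- list(measured = measured_last)
      if (!is.na(calc_last)) candidates$calculated <- calc_last
      for (which_value in names(candidates)) {
        v <- candidates[[which_value]]
        fl <- check_compliance(v, key$unit, key$basis, spec, basis_ctx)
        fl$value_kind <- which_value
        fl$corrected <- FALSE
        compliance[[length(compliance) + 1]] <- fl
        if (!is.na(bw_factor) && spec$kind == "ML") {
          vc <- apply_matrix_correction(v, bw_factor)
          flc <- check_compliance(vc, key$unit, key$basis, spec, basis_ctx)
          flc$value_kind <- which_value
          flc$corrected <- TRUE
          flc$basis_note <- paste0(flc$basis_note,
                                   sprintf("; breathing-water corrected x%.4g",
                                           bw_factor))
          compliance[[length(compliance) + 1]] <- flc
          notes <- c(notes, sprintf("%s value x %.4g (breathing water)",
                                    which_value, bw_factor))
        }
      }
    }
    if (nrow(specs) == 0) notes <- c(notes, "no applicable threshold")
  } else {
    notes <- c(notes, "no matrix class mapped; compliance not evaluated")
  }
  divergence <- lin$calc_vs_measured_factor
  structure(list(
    site = key$site, species = key$species, tissue = key$tissue,
    analyte = key$analyte, unit = key$unit, basis = key$basis,
    n = n, year_first = series$years[1], year_last = series$years[n],
    trend = tr, linear = lin,
    value_last_measured = measured_last,
    value_last_calculated = calc_last,
    last_year_status = lin$last_year_status,
    breathing_water_factor = bw_factor,
    corrected_last_measured = if (!is.na(bw_factor))
      apply_matrix_correction(measured_last, bw_factor) else NA_real_,
    compliance = compliance,
    divergence_flag = !is.na(divergence) && divergence >= divergence_factor,
    divergence_factor = divergence,
    notes = notes
  ), class = "assessment_row")
}

#' Assess a collection of sample records
#'
#' Builds time series from the records and assesses each one. Per-series
#' failures (e.g. too few points for any trend) mark the row
#' `not_assessable` instead of aborting the whole table.
#'
#' @param records validated sample-record data frame.
#' @param context a [read_context()] list.
#' @param registry a [read_thresholds()] registry.
#' @param ... passed to [assess_series()].
#' @return list of class `assessment_table`: one `assessment_row` (or
#'   not-assessable stub) per series, ordered by site, species, tissue,
#'   analyte.
#' @export
assess_collection <- function(records, context, registry, ...) {
  series <- build_time_series(records)
  ord <- order(vapply(series, function(s)
    paste(s$key$site, s$key$species, s$key$tissue, s$key$analyte), character(1)))
  rows <- lapply(series[ord], function(s) {
    tryCatch(assess_series(s, context, registry, ...),
             error = function(e) {
               structure(list(
                 site = s$key$site, species = s$key$species,
                 tissue = s$key$tissue, analyte = s$key$analyte,
                 n = length(s$years), status = "not_assessable",
                 notes = conditionMessage(e)
               ), class = "assessment_row")
             })
  })
  structure(rows, class = "assessment_table")
}

#' Flatten an assessment table to a data frame
#'
#' One row per series with the headline columns of a monitoring assessment
#' table: period, n, trend direction and p-values, last-year measured and
#' calculated values, breathing-water-corrected value, worst compliance
#' status and ratio, and the divergence flag.
#'
#' @param x an [assess_collection()] result.
#' @param ... unused.
#' @return data frame.
#' @export
as.data.frame.assessment_table <- function(x, ...) {
  rows <- lapply(x, function(r) {
    if (!is.null(r$status) && identical(r$status, "not_assessable")) {
      return(data.frame(
        site = r$site, species = r$species, tissue = r$tissue,
        analyte = r$analyte, n = r$n, year_first = NA_integer_,
        year_last = NA_integer_, trend = "not_assessable",
        p_linear = NA_real_, p_nonlinear = NA_real_,
        value_last_measured = NA_real_, value_last_calculated = NA_real_,
        last_year_status = NA_character_, bw_factor = NA_real_,
        worst_status = "not_assessable", worst_ratio = NA_real_,
        divergence_flag = NA, notes = paste(r$notes, collapse = "; "),
        stringsAsFactors = FALSE
      ))
    }
    ratios <- vapply(r$compliance, function(f) {
      if (is.na(f$ratio)) -Inf else f$ratio
    }, numeric(1))
    statuses <- vapply(r$compliance, function(f) f$status, character(1))
    worst <- if (length(ratios) == 0) NA_integer_ else which.max(ratios)
    data.frame(
      site = r$site, species = r$species, tissue = r$tissue,
      analyte = r$analyte, n = r$n, year_first = r$year_first,
      year_last = r$year_last,
      trend = if (is.null(r$trend)) "n<7" else r$trend$overall_trend,
      p_linear = if (is.null(r$trend)) NA_real_ else r$trend$p_linear,
      p_nonlinear = if (is.null(r$trend)) NA_real_ else r$trend$p_nonlinear,
      value_last_measured = r$value_last_measured,
      value_last_calculated = if (is.na(r$value_last_calculated))
        NA_real_ else r$value_last_calculated,
      last_year_status = r$last_year_status,
      bw_factor = r$breathing_water_factor,
      worst_status = if (is.na(worst[1])) "no_threshold" else statuses[worst],
      worst_ratio = if (is.na(worst[1])) NA_real_ else r$compliance[[worst]]$ratio,
      divergence_flag = r$divergence_flag,
      notes = paste(r$notes, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.assessment_table <- function(x, ...) {
  df <- as.data.frame(x)
  cat("Assessment table:", nrow(df), "series\n")
  print(utils::head(df[, c("site", "analyte", "n", "trend", "last_year_status",
                           "worst_status", "worst_ratio")], 20))
  invisible(x)
}
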