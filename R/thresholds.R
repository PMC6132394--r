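## Registry of regulatory reference values and compliance comparison.
## Kinds: ML (food maximum level), EQS (WFD biota environmental quality
## standard), EAC (OSPAR environmental assessment criterion), national_QS.

#' Load a threshold registry
#'
#' Registries are JSON files with a `thresholds` array; each entry carries
#' analyte, matrix_class, value, unit, basis (wet or dry), kind, an optional
#' protection_goal and a source citation. The bundled default registry holds
#' the food maximum levels of Reg. (EC) No 1881/2006 (as amended) for
#' bivalves and fish muscle together with biota EQS, the OSPAR TBT EAC and
#' national quality standards.
#'
#' @param path path to a registry JSON file; default is the bundled registry.
#' @return data frame of class `threshold_registry`.
#' @export
read_thresholds <- function(path = system.file("extdata", "thresholds_default.json",
                                               package = "d9assess")) {
  if (!file.exists(path)) stop("threshold registry not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  tab <- raw$thresholds
  required <- c("analyte", "matrix_class", "value", "unit", "basis", "kind", "source")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("threshold registry schema error: missing field(s) ",
         paste(missing, collapse = ", "))
  }
  if (any(!is.finite(tab$value)) || any(tab$value <= 0)) {
    stop("threshold values must be finite and > 0")
  }
  if (any(!(tab$basis %in% c("wet", "dry")))) {
    stop("threshold basis must be 'wet' or 'dry'")
  }
  tab$unit <- normalize_unit(tab$unit)
  if (is.null(tab$protection_goal)) tab$protection_goal <- NA_character_
  class(tab) <- c("threshold_registry", "data.frame")
  tab
}

#' Look up a threshold
#'
#' @param registry a [read_thresholds()] registry.
#' @param analyte analyte identifier.
#' @param matrix_class matrix class, e.g. `"bivalve"` or `"fish_muscle"`.
#' @param kind threshold kind (`ML`, `EQS`, `EAC`, `national_QS`); omit to
#'   require a unique match across kinds.
#' @return single-row threshold spec (list).
#' @export
lookup_threshold <- function(registry, analyte, matrix_class, kind = NULL) {
  hit <- registry$analyte == analyte & registry$matrix_class == matrix_class
  if (!is.null(kind)) hit <- hit & registry$kind == kind
  n <- sum(hit)
  if (n == 0) {
    stop("no threshold found for ", analyte, " / ", matrix_class,
         if (!is.null(kind)) paste0(" / ", kind))
  }
  if (n > 1) {
    stop("ambiguous threshold lookup for ", analyte, " / ", matrix_class,
         ": ", n, " matches (specify kind)")
  }
  as.list(registry[hit, , drop = FALSE])
}

#' All thresholds applicable to an analyte and matrix class
#'
#' @inheritParams lookup_threshold
#' @return data frame of matching registry rows (possibly empty).
#' @export
applicable_thresholds <- function(registry, analyte, matrix_class) {
  registry[registry$analyte == analyte & registry$matrix_class == matrix_class, ,
           drop = FALSE]
}

#' Check a concentration against a threshold
#'
#' The measured value and the threshold are reconciled to a common unit and
#' basis before the ratio is formed. A dry-weight threshold is converted to
#' wet weight through the tissue water fraction in `context` (and vice
#' versa). Exceedance requires a ratio strictly greater than 1; a value equal
#' to its threshold is compliant. When the bases differ and no water fraction
#' is available the result is `not_assessable`.
#'
#' @param value measured concentration.
#' @param unit unit of `value` (see [normalize_unit()]).
#' @param basis `"wet"` or `"dry"` basis of `value`.
#' @param spec threshold spec from [lookup_threshold()] (or one registry row
#'   as a list).
#' @param context list with optional `water_fraction` used for basis
#'   reconciliation.
#' @return list of class `compliance_flag` with `status` (`compliant`,
#'   `exceedance` or `not_assessable`), `ratio`, `threshold_common` (the
#'   threshold on the value's unit/basis) and `basis_note` recording any
#'   conversion applied.
#' @export
check_compliance <- function(value, unit, basis, spec, context = list()) {
  unit <- normalize_unit(unit)
  notes <- character(0)
  thr <- convert_unit(spec$value, spec$unit, unit)
  if (spec$unit != unit) {
    notes <- c(notes, paste0("threshold converted ", spec$unit, " -> ", unit))
  }
  if (!identical(spec$basis, basis)) {
    w <- context$water_fraction
    if (is.null(w) || is.na(w)) {
      return(structure(list(status = "not_assessable", ratio = NA_real_,
                            threshold_common = NA_real_,
                            basis_note = paste0("basis mismatch (", basis, " vs ",
                                                spec$basis,
                                                ") and no water fraction in context"),
                            spec = spec),
                       class = "compliance_flag"))
    }
    if (spec$basis == "dry" && basis == "wet") {
      thr <- threshold_dw_to_ww(thr, w)
      notes <- c(notes, sprintf("threshold dw -> ww with water fraction %.4g", w))
    } else if (spec$basis == "wet" && basis == "dry") {
      thr <- wet_to_dry(thr, w)
      notes <- c(notes, sprintf("threshold ww -> dw with water fraction %.4g", w))
    } else {
      return(structure(list(status = "not_assessable", ratio = NA_real_,
                            threshold_common = NA_real_,
                            basis_note = paste0("cannot reconcile basis ", basis,
                                                " with ", spec$basis),
                            spec = spec),
                       class = "compliance_flag"))
    }
  }
  ratio <- as.numeric(value) / thr
  structure(list(
    status = if (ratio > 1) "exceedance" else "compliant",
    ratio = ratio,
    threshold_common = thr,
    basis_note = if (length(notes) > 0) paste(notes, collapse = "; ") else "no conversion",
    spec = spec
  ), class = "compliance_flag")
}

#' @export
print.compliance_flag <- function(x, ...) {
  cat(sprintf("%s: ratio %.3g vs %s %s (%s)\n", x$status, x$ratio,
              x$spec$kind, x$spec$analyte, x$basis_note))
  invisible(x)
}

#' Exceedance factor between two protection-goal thresholds
#'
#' Reports how many times higher one threshold is than another, as the
#' integer part of the ratio — the convention used when describing
#' order-of-magnitude margins between, e.g., a human-health quality standard
#' and a secondary-poisoning EQS for the same substance.
#'
#' @param higher,lower threshold values on a common basis.
#' @return list with `ratio` (exact) and `factor` (integer part).
#' @export
threshold_ratio <- function(higher, lower) {
  r <- higher / lower
  list(ratio = r, factor = floor(r))
}
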