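## Basis and matrix conversions. All operations act on the concentration
## scale and are positively homogeneous of degree 1; rounding belongs to the
## report layer only (format_factor, format_eac).

#' Breathing-water dilution factor
#'
#' Mussel soft-body pool samples retain respiration water, diluting tissue
#' concentrations. If the retained water makes up a fraction `b` of the
#' sample wet weight, the undiluted concentration is the measured one times
#' `1/(1-b)`. The factor is returned unrounded; presentation rounding to one
#' decimal happens only in reports.
#'
#' @param b breathing-water fraction of sample wet weight, in `[0, 1)`.
#' @return dilution correction factor `>= 1`.
#' @export
#' @examples
#' breathing_water_factor(0.58) # ~2.38, reported as 2.4
#' breathing_water_factor(0.67) # ~3.03, reported as 3
breathing_water_factor <- function(b) {
  if (any(!is.finite(b)) || any(b < 0) || any(b >= 1)) {
    stop("breathing-water fraction must lie in [0, 1)")
  }
  1 / (1 - b)
}

#' Apply a matrix correction factor
#'
#' @param value concentration(s).
#' @param factor correction factor, `>= 1` (e.g. from
#'   [breathing_water_factor()]).
#' @return corrected concentration `value * factor`.
#' @export
apply_matrix_correction <- function(value, factor) {
  if (any(!is.finite(factor)) || any(factor < 1)) {
    stop("matrix correction factor must be >= 1")
  }
  value * factor
}

#' Convert a dry-weight threshold to wet weight
#'
#' A threshold expressed per dry mass is converted to the wet-weight scale of
#' the monitored tissue via its water fraction `w`:
#' `threshold_ww = threshold_dw * (1 - w)`.
#'
#' @param threshold_dw threshold on dry-weight basis.
#' @param w water fraction of the tissue, in `[0, 1)`.
#' @return threshold on wet-weight basis.
#' @export
#' @examples
#' threshold_dw_to_ww(12, 0.906) # OSPAR TBT EAC for mussels -> ~1.13 ug/kg ww
threshold_dw_to_ww <- function(threshold_dw, w) {
  if (any(!is.finite(w)) || any(w < 0) || any(w >= 1)) {
    stop("water fraction must lie in [0, 1)")
  }
  threshold_dw * (1 - w)
}

#' Convert a wet-weight concentration to dry weight
#'
#' Exact inverse of [threshold_dw_to_ww()]: `c_dw = c_ww / (1 - w)`.
#'
#' @param c_ww concentration on wet-weight basis.
#' @param w water fraction in `[0, 1)`.
#' @return concentration on dry-weight basis.
#' @export
wet_to_dry <- function(c_ww, w) {
  if (any(!is.finite(w)) || any(w < 0) || any(w >= 1)) {
    stop("water fraction must lie in [0, 1)")
  }
  c_ww / (1 - w)
}

#' Lipid-normalize a wet-weight concentration
#'
#' Expresses a concentration per unit lipid mass, `c_ww / l`. Useful for
#' comparing lipophilic contaminants across species with different fat
#' contents.
#'
#' @param c_ww concentration on wet-weight basis.
#' @param l lipid fraction of the tissue, in `(0, 1)`.
#' @return concentration per lipid mass.
#' @export
lipid_normalize <- function(c_ww, l) {
  if (any(!is.finite(l)) || any(l <= 0) || any(l >= 1)) {
    stop("lipid fraction must lie in (0, 1)")
  }
  c_ww / l
}

#' Presentation rounding for correction factors and thresholds
#'
#' Reporting conventions used in assessment tables: breathing-water factors
#' are shown with one decimal, dropping a trailing ".0" (2.4, 3); converted
#' wet-weight assessment criteria with two decimals. Stored values are never
#' rounded — these helpers format for display only.
#'
#' @param factor numeric correction factor.
#' @return character representation.
#' @export
format_factor <- function(factor) {
  r <- round(factor, 1)
  ifelse(r == round(r), format(round(r)), format(r))
}

#' @rdname format_factor
#' @param eac_ww numeric wet-weight criterion.
#' @export
format_eac <- function(eac_ww) {
  format(round(eac_ww, 2))
}
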