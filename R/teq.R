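## WHO toxic-equivalent aggregation of censored congener panels.

#' Load a toxic-equivalency-factor (TEF) table
#'
#' TEF tables are JSON files mapping congener identifiers to a TEF weight and
#' a congener class (`dioxin`, `furan`, `dl-pcb`). The package bundles the
#' WHO-2005 consensus table; alternative tables can be supplied via `path`.
#'
#' @param path path to a TEF JSON file; default is the bundled WHO-2005 table.
#' @return object of class `tef_table`: data frame with columns
#'   `congener_id`, `tef`, `class`, plus a `provenance` attribute.
#' @export
read_tef_table <- function(path = system.file("extdata", "tef_who2005.json",
                                              package = "d9assess")) {
  if (!file.exists(path)) stop("TEF table not found: ", path)
  raw <- jsonlite::fromJSON(path)
  if (is.null(raw$tefs)) stop("TEF file must contain a 'tefs' mapping")
  tab <- data.frame(
    congener_id = names(raw$tefs),
    tef = vapply(raw$tefs, function(x) as.numeric(x$tef), numeric(1)),
    class = vapply(raw$tefs, function(x) as.character(x$class), character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (any(tab$tef <= 0)) stop("all TEF values must be > 0")
  ref <- tab$tef[tab$congener_id == "2378-TCDD"]
  if (length(ref) == 1 && ref != 1) {
    stop("reference congener 2378-TCDD must have TEF 1")
  }
  attr(tab, "provenance") <- if (!is.null(raw$provenance)) raw$provenance else "unspecified"
  class(tab) <- c("tef_table", "data.frame")
  tab
}

#' Construct a congener measurement panel
#'
#' @param congener_id character identifiers (must appear in the TEF table
#'   used for aggregation).
#' @param value concentrations `>= 0` (pg/g wet weight); for censored entries
#'   the value is the limit of quantification (LOQ).
#' @param censored logical; `TRUE` means the measurement was below or equal
#'   to the LOQ and `value` is that LOQ.
#' @return data frame of class `congener_panel`.
#' @export
congener_panel <- function(congener_id, value, censored = rep(FALSE, length(value))) {
  if (length(congener_id) == 0) stop("empty congener panel")
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("congener concentrations must be finite and >= 0")
  }
  out <- data.frame(congener_id = as.character(congener_id),
                    value = as.numeric(value),
                    censored = as.logical(censored),
                    stringsAsFactors = FALSE)
  class(out) <- c("congener_panel", "data.frame")
  out
}

## Substituted concentration for one bound convention: censored entries are
## counted at LOQ (upper), LOQ/2 (middle) or 0 (lower); measured entries
## always enter at their measured value.
.bound_values <- function(panel, bound) {
  bound <- match.arg(bound, c("upper", "middle", "lower"))
  mult <- c(upper = 1, middle = 0.5, lower = 0)[[bound]]
  ifelse(panel$censored, panel$value * mult, panel$value)
}

#' Compute a WHO toxic equivalent (TEQ) for a congener panel
#'
#' TEQ = sum over congeners of TEF_i * c_i, where censored congeners enter at
#' their LOQ (`bound = "upper"`), half the LOQ (`"middle"`) or zero
#' (`"lower"`). Regulatory comparisons conventionally use the upper bound.
#'
#' @param panel a [congener_panel()].
#' @param tefs a [read_tef_table()] object.
#' @param bound censoring substitution convention.
#' @param classes optional subset of congener classes to aggregate, e.g.
#'   `c("dioxin", "furan")` for a PCDD/F-only TEQ (food maximum levels set
#'   separate limits for PCDD/F and PCDD/F + dl-PCB sums).
#' @return TEQ concentration (pg/g WHO-TEQ) with attributes `bound` and
#'   `tef_provenance`.
#' @export
#' @examples
#' tefs <- read_tef_table()
#' p <- congener_panel(c("2378-TCDD", "PCB-126"), c(0.5, 0.1), c(FALSE, TRUE))
#' compute_teq(p, tefs, "upper")  # 0.5 + 0.1*0.1 = 0.51
compute_teq <- function(panel, tefs, bound = c("upper", "middle", "lower"),
                        classes = NULL) {
  bound <- match.arg(bound)
  if (nrow(panel) == 0) stop("empty congener panel")
  idx <- match(panel$congener_id, tefs$congener_id)
  if (anyNA(idx)) {
    stop("congener(s) missing from TEF table: ",
         paste(unique(panel$congener_id[is.na(idx)]), collapse = ", "))
  }
  keep <- if (is.null(classes)) rep(TRUE, nrow(panel)) else tefs$class[idx] %in% classes
  teq <- sum(tefs$tef[idx][keep] * .bound_values(panel[keep, , drop = FALSE], bound))
  structure(teq, bound = bound, tef_provenance = attr(tefs, "provenance"),
            class = "teq")
}

#' @export
print.teq <- function(x, ...) {
  cat(sprintf("%s-bound TEQ: %g pg/g WHO-TEQ [%s]\n", attr(x, "bound"),
              as.numeric(x), attr(x, "tef_provenance")))
  invisible(x)
}

#' Sum congener concentrations under a censoring bound
#'
#' Plain (unweighted) sum of a congener panel under the same upper/middle/
#' lower-bound censoring conventions as [compute_teq()]; used for sums such
#' as the six indicator non-dioxin-like PCBs.
#'
#' @inheritParams compute_teq
#' @return summed concentration with attribute `bound`.
#' @export
sum_congeners <- function(panel, bound = c("upper", "middle", "lower")) {
  bound <- match.arg(bound)
  if (nrow(panel) == 0) stop("empty congener panel")
  structure(sum(.bound_values(panel, bound)), bound = bound)
}
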