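## Seeded generators of synthetic monitoring data with the statistical
## structure the assessment assumes: one annual pool value per site x
## species x analyte x year, multiplicative lognormal noise, exponential
## decline or hump-shaped trends, and left-censoring at an LOQ.

#' Specification of a synthetic annual pool series
#'
#' The mean concentration follows
#' `c(t) = c0 * exp(-k * t) + hump(t)` with `t` the years since
#' `year_start`; the optional hump term is a Gaussian bump of amplitude
#' `nonlinear_amplitude` centred mid-series (width one quarter of the span),
#' giving rise-then-fall shapes. Observed values are `c(t)` times lognormal
#' noise with coefficient of variation `noise_cv` (so the noise is
#' scale-free); values below `loq` are reported at the LOQ and flagged
#' censored.
#'
#' @param year_start,year_end first and last sampling year.
#' @param sampling_interval years between pools (1 = annual, 2 = biennial).
#' @param c0 initial mean concentration (> 0).
#' @param decline_rate exponential decline rate k per year (0 = flat).
#' @param nonlinear_amplitude amplitude of the hump term (0 = none).
#' @param noise_cv lognormal coefficient of variation of the noise (>= 0).
#' @param loq left-censoring limit (0 = no censoring).
#' @param site,species,tissue,analyte,unit,basis record metadata.
#' @param water_fraction,lipid_fraction,breathing_water_fraction optional
#'   fractions copied onto each record.
#' @return list of class `series_spec`.
#' @export
series_spec <- function(year_start = 1985, year_end = 2017,
                        sampling_interval = 1,
                        c0 = 1, decline_rate = 0, nonlinear_amplitude = 0,
                        noise_cv = 0.2, loq = 0,
                        site = "S1", species = "Mytilus edulis",
                        tissue = "soft body", analyte = "X",
                        unit = "µg/kg", basis = "wet",
                        water_fraction = NA_real_, lipid_fraction = NA_real_,
                        breathing_water_fraction = NA_real_) {
  if (c0 <= 0) stop("c0 must be > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (year_end < year_start) stop("year_end must be >= year_start")
  if (!sampling_interval %in% c(1, 2)) stop("sampling_interval must be 1 or 2")
  structure(as.list(environment()), class = "series_spec")
}

## Deterministic mean curve of a spec at years since start t.
.mean_curve <- function(spec, t) {
  span <- max(spec$year_end - spec$year_start, 1)
  hump <- spec$nonlinear_amplitude *
    exp(-((t - span / 2)^2) / (2 * (span / 4)^2))
  spec$c0 * exp(-spec$decline_rate * t) + hump
}

#' Simulate an annual pool monitoring series
#'
#' Draws one sample record per sampling year according to a [series_spec()],
#' reproducibly for a given seed. Lognormal noise is parameterized so that
#' the multiplicative factor has mean 1 and coefficient of variation
#' `noise_cv`. Values falling below the LOQ are emitted at the LOQ with
#' `censored = TRUE`.
#'
#' @param spec a [series_spec()].
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return list with `records` (a validated sample-record data frame),
#'   `series` (the corresponding [time_series()]) and `truth` (a list with
#'   the mean curve `mean`, the `years`, the uncensored draws `raw`, and
#'   `n_censored`).
#' @export
simulate_series <- function(spec, seed = 1) {
  seed <- as.integer(seed)  # force before saving RNG state (lazy evaluation)
  years <- seq(spec$year_start, spec$year_end, by = spec$sampling_interval)
  t <- years - spec$year_start
  mu <- .mean_curve(spec, t)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  noise <- if (spec$noise_cv == 0) rep(1, length(years)) else
    stats::rlnorm(length(years), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  raw <- mu * noise
  censored <- raw < spec$loq
  value <- ifelse(censored, spec$loq, raw)
  records <- data.frame(
    site = spec$site, species = spec$species, tissue = spec$tissue,
    year = as.integer(years), analyte = spec$analyte, value = value,
    unit = spec$unit, basis = spec$basis, censored = censored,
    water_fraction = spec$water_fraction,
    lipid_fraction = spec$lipid_fraction,
    breathing_water_fraction = spec$breathing_water_fraction,
    stringsAsFactors = FALSE
  )
  validate_samples(records)
  class(records) <- c("sample_records", "data.frame")
  list(
    records = records,
    series = time_series(years, value, censored,
                         key = list(site = spec$site, species = spec$species,
                                    tissue = spec$tissue, analyte = spec$analyte,
                                    basis = spec$basis, unit = spec$unit)),
    truth = list(years = years, mean = mu, raw = raw,
                 n_censored = sum(censored))
  )
}

#' Simulate a censored congener panel
#'
#' Draws `n_congeners` lognormal concentrations from the bundled WHO-2005
#' congener list (recycled if more congeners are requested than the table
#' holds), censors each with probability `censor_prob` at an LOQ drawn above
#' the value, and records the ground-truth upper/middle/lower TEQs computed
#' by direct summation for cross-checking.
#'
#' @param n_congeners number of congeners to draw (default: all 29 of the
#'   WHO-2005 table).
#' @param censor_prob probability that a congener is reported censored.
#' @param seed integer seed.
#' @param meanlog,sdlog lognormal parameters of the concentration draws.
#' @return list with `panel` (a [congener_panel()]), `tefs` (the table used)
#'   and `truth` (`teq_upper`, `teq_middle`, `teq_lower`, `n_censored`).
#' @export
simulate_congener_panel <- function(n_congeners = NULL, censor_prob = 0.3,
                                    seed = 1, meanlog = 0, sdlog = 1) {
  seed <- as.integer(seed)  # force before saving RNG state (lazy evaluation)
  if (censor_prob < 0 || censor_prob > 1) stop("censor_prob must lie in [0, 1]")
  tefs <- read_tef_table()
  ids <- tefs$congener_id
  if (!is.null(n_congeners)) {
    ids <- rep_len(ids, n_congeners)
    ids <- make.unique(ids)
    tefs <- tefs[match(sub("\\.[0-9]+$", "", ids), tefs$congener_id), ]
    tefs$congener_id <- ids
    class(tefs) <- c("tef_table", "data.frame")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  conc <- stats::rlnorm(length(ids), meanlog, sdlog)
  censored <- stats::runif(length(ids)) < censor_prob
  ## for censored congeners the reported value is an LOQ at or above the
  ## (unobserved) concentration
  loq_mult <- 1 + stats::runif(length(ids), 0, 1)
  value <- ifelse(censored, conc * loq_mult, conc)
  panel <- congener_panel(ids, value, censored)
  tef <- tefs$tef[match(ids, tefs$congener_id)]
  truth <- list(
    teq_upper = sum(tef * value),
    teq_middle = sum(tef * ifelse(censored, value / 2, value)),
    teq_lower = sum(tef * ifelse(censored, 0, value)),
    n_censored = sum(censored)
  )
  list(panel = panel, tefs = tefs, truth = truth)
}

#' Simulate the packaged demo monitoring campaign
#'
#' Generates a small multi-site campaign mirroring a typical coastal
#' monitoring design: three sites (NS1, NS2, BS) with mussel soft-body
#' series (1985-2017, site-specific water contents 0.906/0.926/0.947 and
#' breathing-water fractions 0.67/0.58/0.67) and eelpout fillet series
#' (1994-2017) for a handful of analytes with declining, flat or hump-shaped
#' trends. Concentration scales are order-of-magnitude plausible for coastal
#' biota; they are not calibrated to any particular dataset.
#'
#' @param seed integer seed.
#' @return validated `sample_records` data frame covering all series.
#' @export
simulate_demo_campaign <- function(seed = 42) {
  sites <- list(
    NS1 = list(w = 0.906, b = 0.67),
    NS2 = list(w = 0.926, b = 0.58),
    BS = list(w = 0.947, b = 0.67)
  )
  mussel_analytes <- list(
    ## analyte, unit, c0, decline rate, loq
    list(analyte = "Pb", unit = "mg/kg", c0 = 0.35, k = 0.02, loq = 0.001),
    list(analyte = "Cd", unit = "mg/kg", c0 = 0.2, k = 0.015, loq = 0.001),
    list(analyte = "Hg", unit = "mg/kg", c0 = 0.03, k = 0.01, loq = 0.0005),
    list(analyte = "Sum4PAH", unit = "µg/kg", c0 = 18, k = 0.06, loq = 0.1),
    list(analyte = "TBT", unit = "µg/kg", c0 = 40, k = 0.12, loq = 0.2)
  )
  fish_analytes <- list(
    list(analyte = "PFOS", unit = "µg/kg", c0 = 4, k = 0.03, loq = 0.05),
    list(analyte = "PBDE", unit = "µg/kg", c0 = 0.3, k = 0.08, loq = 0.001),
    list(analyte = "HBCDD", unit = "µg/kg", c0 = 1.2, k = 0.05, loq = 0.01),
    list(analyte = "Hg", unit = "mg/kg", c0 = 0.08, k = 0.005, loq = 0.0005)
  )
  out <- list()
  i <- 0
  for (s in names(sites)) {
    for (a in mussel_analytes) {
      i <- i + 1
      sp <- series_spec(1985, 2017, 1, c0 = a$c0, decline_rate = a$k,
                        noise_cv = 0.25, loq = a$loq, site = s,
                        species = "Mytilus edulis", tissue = "soft body",
                        analyte = a$analyte, unit = a$unit,
                        water_fraction = sites[[s]]$w,
                        breathing_water_fraction = sites[[s]]$b)
      out[[i]] <- simulate_series(sp, seed = seed + i)$records
    }
    for (a in fish_analytes) {
      i <- i + 1
      sp <- series_spec(1994, 2017, 1, c0 = a$c0, decline_rate = a$k,
                        noise_cv = 0.25, loq = a$loq, site = s,
                        species = "Zoarces viviparus", tissue = "fillet",
                        analyte = a$analyte, unit = a$unit)
      out[[i]] <- simulate_series(sp, seed = seed + i)$records
    }
  }
  records <- do.call(rbind, out)
  class(records) <- c("sample_records", "data.frame")
  records
}

## Save/restore the global RNG state so simulation helpers are reproducible
## without clobbering the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
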