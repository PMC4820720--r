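#' Nuclide constants for the 90Sr/90Y pair
#'
#' Bundles the half-lives and the reference date used for decay correction.
#' The 90Sr half-life is 28.8 y; the 90Y half-life defaults to 64.05 h
#' (standard nuclear data). Decay constants are derived as
#' \eqn{\lambda = \ln 2 / T_{1/2}} on the scales the rest of the package
#' uses (per year and per hour).
#'
#' @param halflife_sr90_yr Half-life of 90Sr in years.
#' @param halflife_y90_hr Half-life of 90Y in hours.
#' @param reference_date Calendar date all activities are decay-corrected
#'   to (the accident date, 2011-03-11, by default).
#' @return An object of class `nuclide_constants`: a list with the
#'   half-lives, the reference date, and decay constants `lambda_sr_yr`,
#'   `lambda_sr_hr`, `lambda_y_hr`.
#' @examples
#' nc <- nuclide_constants()
#' log(2) / nc$lambda_sr_yr # 28.8
#' @export
nuclide_constants <- function(halflife_sr90_yr = 28.8,
                              halflife_y90_hr = 64.05,
                              reference_date = as.Date("2011-03-11")) {
  stopifnot(is.numeric(halflife_sr90_yr), halflife_sr90_yr > 0,
            is.numeric(halflife_y90_hr), halflife_y90_hr > 0)
  reference_date <- as.Date(reference_date)
  structure(
    list(
      halflife_sr90_yr = halflife_sr90_yr,
      halflife_y90_hr = halflife_y90_hr,
      reference_date = reference_date,
      lambda_sr_yr = log(2) / halflife_sr90_yr,
      lambda_sr_hr = log(2) / (halflife_sr90_yr * 365.25 * 24),
      lambda_y_hr = log(2) / halflife_y90_hr
    ),
    class = "nuclide_constants"
  )
}

#' Counter calibration for low-background beta counting
#'
#' Describes one gas-flow counter: detection efficiency measured against a
#' standard source at a reference precipitate thickness, the background
#' rate and the duration of the background run, the fitted self-absorption
#' coefficient, and the equilibrium count multiplier (counts registered
#' per 90Sr decay once 90Y is in secular equilibrium; 2 when both beta
#' emitters are counted with equal efficiency).
#'
#' Efficiency is defined *at* the standard thickness, so self-absorption
#' corrections apply only to deviations from that thickness (see
#' [self_absorption_factor()]).
#'
#' @param efficiency Counts detected per decay at the standard thickness,
#'   in (0, 1). Default 0.339.
#' @param efficiency_standard_activity Activity of the efficiency
#'   standard, Bq.
#' @param efficiency_standard_thickness Areal thickness of the efficiency
#'   standard, mg cm^-2.
#' @param background_rate Background counting rate, cpm.
#' @param background_duration Duration of the background determination,
#'   minutes (720 = 12 h).
#' @param absorption_coefficient Self-absorption coefficient mu,
#'   cm^2 mg^-1.
#' @param equilibrium_count_multiplier Counts per 90Sr decay at secular
#'   equilibrium, in [1, 2].
#' @return An object of class `assay_calibration`.
#' @export
assay_calibration <- function(efficiency = 0.339,
                              efficiency_standard_activity = 88.4,
                              efficiency_standard_thickness = 24,
                              background_rate = 0.155,
                              background_duration = 720,
                              absorption_coefficient = 0.005,
                              equilibrium_count_multiplier = 2) {
  if (!(efficiency > 0 && efficiency < 1))
    stop("efficiency must lie in (0, 1)")
  if (background_rate < 0)
    stop("background_rate must be >= 0")
  if (background_duration <= 0)
    stop("background_duration must be positive")
  if (!(equilibrium_count_multiplier >= 1 && equilibrium_count_multiplier <= 2))
    stop("equilibrium_count_multiplier must lie in [1, 2]")
  if (absorption_coefficient < 0)
    stop("absorption_coefficient must be >= 0")
  structure(
    list(
      efficiency = efficiency,
      efficiency_standard_activity = efficiency_standard_activity,
      efficiency_standard_thickness = efficiency_standard_thickness,
      background_rate = background_rate,
      background_duration = background_duration,
      absorption_coefficient = absorption_coefficient,
      equilibrium_count_multiplier = equilibrium_count_multiplier
    ),
    class = "assay_calibration"
  )
}

#' Write or read a counter calibration as YAML
#'
#' @param calib An [assay_calibration()] object.
#' @param path File path of the YAML record.
#' @return `read_calibration()` returns an `assay_calibration`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "assay_calibration"))
  yaml::write_yaml(unclass(calib), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(assay_calibration, x[names(x) %in% names(formals(assay_calibration))])
}
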