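#' Concentration by the standard-addition method
#'
#' Known increments of analyte are spiked into aliquots of the diluted
#' sample solution and the emission intensity is regressed on the added
#' concentration. The native solution concentration is the (positive)
#' x-axis intercept, intercept/slope. The result is converted to a
#' per-gram-of-ash concentration through the dilution factor and the
#' dissolution geometry (mass of ash dissolved in a known volume).
#' Standard addition is robust to matrix effects, which is why it is the
#' method of choice for Sr in a Ca-dominated matrix.
#'
#' @param added_conc Added analyte concentrations, ug L^-1 (>= 2 distinct
#'   values, one of them usually 0).
#' @param intensity Measured intensities, arbitrary units.
#' @param dilution_factor Dilution applied to the dissolved sample before
#'   measurement (default 10000).
#' @param solution_volume_l Volume the ash was dissolved in, L (default
#'   0.010 = 10 mL).
#' @param ash_mass_g Mass of ash dissolved, g.
#' @return List with `conc_diluted_ug_l` (native concentration in the
#'   measured solution), `conc_ug_per_g` (per g ash), `slope`,
#'   `intercept`.
#' @examples
#' standard_addition_concentration(c(0, 1, 2), c(10, 20, 30))
#' @export
standard_addition_concentration <- function(added_conc, intensity,
                                            dilution_factor = 10000,
                                            solution_volume_l = 0.010,
                                            ash_mass_g = 1) {
  x <- as.numeric(added_conc)
  y <- as.numeric(intensity)
  if (length(x) != length(y)) stop("lengths differ")
  if (length(unique(x)) < 2)
    stop("all additions identical: concentration unidentifiable")
  if (any(y < 0)) stop("intensities must be nonnegative")
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit)[2])
  a <- unname(stats::coef(fit)[1])
  if (b <= 0) stop("nonpositive response slope: calibration failure")
  conc <- a / b
  list(
    conc_diluted_ug_l = conc,
    conc_ug_per_g = conc * dilution_factor * solution_volume_l / ash_mass_g,
    slope = b,
    intercept = a
  )
}

#' Concentration by a calibration curve
#'
#' External standards of known concentration define a linear
#' intensity-concentration response; the sample concentration is read
#' off by inverse prediction. Conversion to a per-gram-of-ash value uses
#' the same dilution/dissolution bookkeeping as
#' [standard_addition_concentration()].
#'
#' @param standard_conc Standard concentrations, ug L^-1 (>= 2 distinct).
#' @param intensity Standard intensities.
#' @param sample_intensity Intensity (or intensities) of the sample
#'   solution.
#' @inheritParams standard_addition_concentration
#' @return List with `conc_diluted_ug_l`, `conc_ug_per_g` (both
#'   vectorised over `sample_intensity`), `slope`, `intercept`. Warns
#'   when the sample intensity falls outside the standard range.
#' @examples
#' calibration_curve_concentration(c(0, 10), c(0, 100), 50)
#' @export
calibration_curve_concentration <- function(standard_conc, intensity,
                                            sample_intensity,
                                            dilution_factor = 10000,
                                            solution_volume_l = 0.010,
                                            ash_mass_g = 1) {
  x <- as.numeric(standard_conc)
  y <- as.numeric(intensity)
  if (length(x) != length(y)) stop("lengths differ")
  if (length(unique(x)) < 2) stop("need >= 2 distinct standards")
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit)[2])
  a <- unname(stats::coef(fit)[1])
  if (abs(b) < .Machine$double.eps^0.5 || b <= 0)
    stop("nonpositive calibration slope")
  if (any(sample_intensity < min(y) - 1e-9 | sample_intensity > max(y) + 1e-9))
    warning("sample intensity outside the standard range: extrapolating")
  conc <- (sample_intensity - a) / b
  list(
    conc_diluted_ug_l = conc,
    conc_ug_per_g = conc * dilution_factor * solution_volume_l / ash_mass_g,
    slope = b,
    intercept = a
  )
}

#' Mean and standard deviation of a triplicate measurement
#'
#' @param values Numeric measurements; nominally three.
#' @return List with `mean`, `sd` (sample sd, n - 1 denominator), `n`,
#'   and `complete` (TRUE when exactly three values were supplied).
#'   Incomplete triplicates are summarised anyway but flagged.
#' @examples
#' triplicate_summary(c(111.6, 113.0, 114.4)) # 113 +/- 1.4
#' @export
triplicate_summary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no values to summarise")
  list(
    mean = mean(values),
    sd = if (n > 1) stats::sd(values) else NA_real_,
    n = n,
    complete = n == 3
  )
}

#' Normalise a 90Sr activity to Ca and stable Sr
#'
#' The two reporting scales of the analysis: the activity concentration
#' (mBq per g Ca), the contamination metric, and the specific activity
#' (Bq per g stable Sr), which isolates isotopic enrichment from
#' elemental Sr uptake.
#'
#' @param activity_mbq Decay-corrected 90Sr activity of the sample, mBq
#'   (vectorised).
#' @param ash_mass_g Ash mass the activity refers to, g.
#' @param sr_ug_g Stable Sr concentration of the ash, ug per g.
#' @param ca_fraction Ca mass fraction of the ash, g per g.
#' @return A tibble with `activity_conc_mbq_g_ca` and
#'   `specific_activity_bq_g_sr`.
#' @examples
#' normalize_activity(100, 1, sr_ug_g = 200, ca_fraction = 0.4)
#' @export
normalize_activity <- function(activity_mbq, ash_mass_g, sr_ug_g,
                               ca_fraction) {
  if (any(ash_mass_g <= 0)) stop("ash mass must be positive")
  if (any(sr_ug_g <= 0)) stop("stable Sr concentration must be positive")
  if (any(ca_fraction <= 0 | ca_fraction >= 1))
    stop("ca_fraction must lie in (0, 1)")
  if (any(activity_mbq < 0)) stop("activity must be >= 0")
  tibble::tibble(
    activity_conc_mbq_g_ca = activity_mbq / (ash_mass_g * ca_fraction),
    specific_activity_bq_g_sr =
      (activity_mbq / 1000) / (ash_mass_g * sr_ug_g * 1e-6)
  )
}
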