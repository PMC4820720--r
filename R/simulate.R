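#' Default simulation scenario
#'
#' A complete description of one synthetic study: the three areas with
#' their soil deposition and pre/post-step environmental levels, the
#' herd (the eight study animals by default), the mineralization window
#' table, biological and assay noise levels, and the laboratory model
#' (counter calibration, yield and thickness distributions, counting
#' schedule, ICP geometry).
#'
#' Environmental levels are expressed as the specific activity (Bq per
#' g stable Sr) a tooth mineralising wholly under that regime would
#' acquire (transfer factor 1). The defaults are calibrated to the
#' per-area ranges the study reports: specific activities of roughly
#' 214-1351 Bq/g Sr in area H, 60-641 in area L and 13-78 in the
#' control area, with the control mean activity concentration near
#' 14 mBq per g Ca. Stable Sr levels rise from ~125 to ~185 ug/g across
#' the feed change in the contaminated areas and stay flat (~190) in
#' the control area.
#'
#' @param herd Herd tibble as from [cattle_table()].
#' @param tooth_status Optional per-tooth status tibble (`animal_id`,
#'   `tooth_class`, `status`); defaults to the missingness pattern of
#'   [stable_sr_table()] so the simulated study has the same usable-n
#'   structure as the real one. Pass `NULL` for a complete dentition.
#' @return A list of class `scenario_config`.
#' @export
default_scenario <- function(herd = cattle_table(),
                             tooth_status = stable_sr_table()[
                               , c("animal_id", "tooth_class", "status")]) {
  structure(list(
    accident_date = as.Date("2011-03-11"),
    areas = tibble::tibble(
      area = c("H", "L", "C"),
      soil_sr90_bq_m2 = c(738, 195, 96),
      env_pre = c(250, 75, 23),
      env_post = c(1200, 550, 23),
      sr_pre_ug_g = c(125, 125, 190),
      sr_post_ug_g = c(185, 185, 190)
    ),
    herd = herd,
    tooth_status = tooth_status,
    windows = development_windows(),
    transfer = 1,
    baseline = 0,
    bio_cv = 0.30,
    sr_tooth_cv = 0.05,
    sr_animal_cv = 0.15,
    ca_mean = 0.31,
    ca_sd = 0.015,
    lab = list(
      efficiency = 0.339,
      efficiency_standard_activity = 88.4,
      efficiency_standard_thickness = 24,
      background_rate = 0.155,
      background_duration = 720,
      absorption_coefficient = 0.005,
      equilibrium_count_multiplier = 2,
      yield_range = c(0.50, 0.96),
      thickness_mean = 24,
      thickness_sd = 3,
      n_counts = c(5L, 6L),
      count_window_hr = 336,
      count_duration_range_min = c(180, 720),
      separation_lag_days = 90,
      dilution_factor = 10000,
      solution_volume_l = 0.010,
      ash_mass_g = 1,
      icp_noise_cv = 0.01,
      sr_additions_ug_l = c(0, 1, 2, 4),
      ca_standards_ug_l = c(0, 1000, 2000, 4000, 6000)
    )
  ), class = "scenario_config")
}

#' Counter calibration implied by a scenario
#'
#' @param scenario A `scenario_config` list.
#' @return An [assay_calibration()] object.
#' @export
scenario_calibration <- function(scenario) {
  l <- scenario$lab
  assay_calibration(
    efficiency = l$efficiency,
    efficiency_standard_activity = l$efficiency_standard_activity,
    efficiency_standard_thickness = l$efficiency_standard_thickness,
    background_rate = l$background_rate,
    background_duration = l$background_duration,
    absorption_coefficient = l$absorption_coefficient,
    equilibrium_count_multiplier = l$equilibrium_count_multiplier
  )
}

# lognormal multiplier with unit mean and the given cv
.ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate the true state of a synthetic study
#'
#' For every animal and tooth class the generator computes the
#' post-step window fraction phi from the mineralization chronology,
#' sets the expected specific activity from the area's step exposure,
#' multiplies in lognormal biological noise, draws the stable Sr
#' concentration (higher for post-accident-formed teeth in the
#' contaminated areas, with animal-level and tooth-level lognormal
#' variation) and the Ca mass fraction, and converts to the per-tooth
#' activity a 1 g ash aliquot would carry at the reference date.
#'
#' @param scenario A `scenario_config` list.
#' @param seed Optional integer seed.
#' @return Truth tibble: `sample_id`, `animal_id`, `area`,
#'   `tooth_class`, `phi`, `sr_ug_g`, `ca_fraction`,
#'   `specific_bq_g_sr`, `activity_mbq_ref`, `activity_conc_mbq_g_ca`,
#'   `status`.
#' @export
simulate_truth <- function(scenario = default_scenario(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  herd <- scenario$herd
  areas <- scenario$areas
  windows <- scenario$windows
  if (any(windows$start_months >= windows$end_months))
    stop("misconfigured windows: start must precede end")
  ash <- scenario$lab$ash_mass_g
  rows <- vector("list", nrow(herd))
  for (i in seq_len(nrow(herd))) {
    an <- herd[i, ]
    ar <- areas[areas$area == an$area, ]
    if (nrow(ar) != 1) stop("animal area not in scenario areas")
    step <- exposure_step(ar$env_pre, ar$env_post, scenario$accident_date)
    tc <- windows$tooth_class
    phi <- post_step_fraction(tc, an$birth_date, scenario$accident_date,
                              windows)
    pred <- predicted_specific_activity(step, tc, an$birth_date,
                                        transfer = scenario$transfer,
                                        windows = windows,
                                        baseline = scenario$baseline)
    spec <- pred * .ln_noise(length(tc), scenario$bio_cv)
    sr_mean <- ar$sr_pre_ug_g + (ar$sr_post_ug_g - ar$sr_pre_ug_g) * phi
    animal_mult <- .ln_noise(1, scenario$sr_animal_cv)
    sr <- sr_mean * animal_mult * .ln_noise(length(tc), scenario$sr_tooth_cv)
    ca <- if (scenario$ca_sd > 0) {
      pmin(pmax(stats::rnorm(length(tc), scenario$ca_mean, scenario$ca_sd),
                0.20), 0.45)
    } else rep(scenario$ca_mean, length(tc))
    act_mbq <- spec * sr * 1e-6 * ash * 1000
    rows[[i]] <- tibble::tibble(
      sample_id = paste(an$animal_id, tc, sep = "_"),
      animal_id = an$animal_id,
      area = an$area,
      tooth_class = tc,
      phi = phi,
      sr_ug_g = sr,
      ca_fraction = ca,
      specific_bq_g_sr = spec,
      activity_mbq_ref = act_mbq,
      activity_conc_mbq_g_ca = act_mbq / (ash * ca)
    )
  }
  truth <- dplyr::bind_rows(rows)
  if (!is.null(scenario$tooth_status)) {
    st <- scenario$tooth_status
    key <- paste(st$animal_id, st$tooth_class, sep = "_")
    truth$status <- st$status[match(truth$sample_id, key)]
    truth$status[is.na(truth$status)] <- "ok"
  } else {
    truth$status <- "ok"
  }
  truth
}

#' Simulate the laboratory record of a synthetic study
#'
#' Forward-models the measurement chain for every usable tooth in a
#' truth table: the sample decays from the reference date to its
#' separation date, a chemical yield and precipitate thickness are
#' drawn, a counting schedule of 5-6 measurements inside a fortnight of
#' the separation is generated, gross counts are Poisson draws around
#' the ingrowth forward model, and ICP intensities for the Sr
#' standard-addition and Ca calibration-curve assays are produced in
#' triplicate with multiplicative noise. With `noise = "none"` all
#' draws are replaced by their expectations (counts then need not be
#' integers), giving an exact end-to-end round trip.
#'
#' @param truth Truth tibble from [simulate_truth()].
#' @param scenario The `scenario_config` that produced it.
#' @param seed Optional integer seed.
#' @param noise `"poisson"` (default) or `"none"`.
#' @return List of tibbles `counts`, `assays`, `samples` in the
#'   pipeline's input schemas.
#' @export
simulate_lab <- function(truth, scenario = default_scenario(), seed = NULL,
                         noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  l <- scenario$lab
  calib <- scenario_calibration(scenario)
  constants <- nuclide_constants()
  herd <- scenario$herd

  ok <- truth[truth$status == "ok", ]
  counts_rows <- vector("list", nrow(ok))
  assay_rows <- vector("list", nrow(ok))
  sample_rows <- vector("list", nrow(ok))
  for (i in seq_len(nrow(ok))) {
    s <- ok[i, ]
    an <- herd[herd$animal_id == s$animal_id, ]
    sampling_date <- an$birth_date +
      round(an$age_sampling_months * 30.4375)
    separation_date <- sampling_date + l$separation_lag_days
    dt_yr <- as.numeric(separation_date - constants$reference_date) / 365.25
    act_sep_bq <- s$activity_mbq_ref / 1000 *
      exp(-constants$lambda_sr_yr * dt_yr)

    yield <- if (noise == "poisson")
      stats::runif(1, l$yield_range[1], l$yield_range[2])
    else mean(l$yield_range)
    thickness <- if (noise == "poisson")
      max(stats::rnorm(1, l$thickness_mean, l$thickness_sd), 5)
    else l$thickness_mean
    n_c <- if (noise == "poisson")
      sample(l$n_counts, 1) else max(l$n_counts)
    t_hours <- sort(stats::runif(n_c, 12, l$count_window_hr))
    duration <- round(stats::runif(n_c, l$count_duration_range_min[1],
                                   l$count_duration_range_min[2]))
    mu_counts <- expected_gross_rate(act_sep_bq * yield, t_hours, thickness,
                                     calib, constants) * duration
    gross <- if (noise == "poisson") stats::rpois(n_c, mu_counts)
             else mu_counts
    counts_rows[[i]] <- tibble::tibble(
      sample_id = s$sample_id, t_hours = t_hours,
      duration_min = duration, gross_counts = gross)

    # ICP forward model: intensities linear in solution concentration
    sr_diluted <- s$sr_ug_g * l$ash_mass_g / l$solution_volume_l /
      l$dilution_factor
    ca_diluted <- s$ca_fraction * 1e6 * l$ash_mass_g / l$solution_volume_l /
      l$dilution_factor
    slope_sr <- 1000
    slope_ca <- 10
    noise_mult <- function(n)
      if (noise == "poisson") 1 + stats::rnorm(n, 0, l$icp_noise_cv)
      else rep(1, n)
    sr_grid <- expand.grid(replicate = 1:3,
                           point_conc = l$sr_additions_ug_l)
    sr_int <- slope_sr * (sr_diluted + sr_grid$point_conc) *
      noise_mult(nrow(sr_grid))
    ca_grid <- expand.grid(replicate = 1:3,
                           point_conc = c(l$ca_standards_ug_l, NA))
    ca_conc_true <- ifelse(is.na(ca_grid$point_conc), ca_diluted,
                           ca_grid$point_conc)
    ca_int <- slope_ca * ca_conc_true * noise_mult(nrow(ca_grid))
    assay_rows[[i]] <- dplyr::bind_rows(
      tibble::tibble(sample_id = s$sample_id, element = "Sr",
                     method = "standard_addition",
                     point_conc = sr_grid$point_conc,
                     intensity = sr_int, replicate = sr_grid$replicate),
      tibble::tibble(sample_id = s$sample_id, element = "Ca",
                     method = "calibration_curve",
                     point_conc = ca_grid$point_conc,
                     intensity = ca_int, replicate = ca_grid$replicate)
    )
    sample_rows[[i]] <- tibble::tibble(
      sample_id = s$sample_id, animal_id = s$animal_id, area = s$area,
      tooth_class = s$tooth_class, ash_mass_g = l$ash_mass_g,
      chemical_yield = yield, thickness_mg_cm2 = thickness,
      separation_date = separation_date, status = "ok")
  }
  missing <- truth[truth$status != "ok", ]
  samples <- dplyr::bind_rows(
    dplyr::bind_rows(sample_rows),
    if (nrow(missing) > 0) tibble::tibble(
      sample_id = missing$sample_id, animal_id = missing$animal_id,
      area = missing$area, tooth_class = missing$tooth_class,
      ash_mass_g = NA_real_, chemical_yield = NA_real_,
      thickness_mg_cm2 = NA_real_, separation_date = as.Date(NA),
      status = missing$status)
  )
  list(counts = dplyr::bind_rows(counts_rows),
       assays = dplyr::bind_rows(assay_rows),
       samples = samples)
}

#' Write or read a simulated study as CSV files
#'
#' Writes `counts.csv`, `assays.csv`, `samples.csv` (and `truth.csv`
#' when supplied) in the pipeline's schemas: UTF-8, comma-separated,
#' header row, NA as empty field with the status column carrying the
#' missingness semantics.
#'
#' @param lab List from [simulate_lab()].
#' @param dir Output directory (created if absent).
#' @param truth Optional truth tibble.
#' @return `write_study()` the directory, invisibly; `read_study()` a
#'   list of tibbles.
#' @export
write_study <- function(lab, dir, truth = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(lab$counts, file.path(dir, "counts.csv"))
  readr::write_csv(lab$assays, file.path(dir, "assays.csv"))
  readr::write_csv(lab$samples, file.path(dir, "samples.csv"))
  if (!is.null(truth)) readr::write_csv(truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  read1 <- function(f) readr::read_csv(file.path(dir, f),
                                       show_col_types = FALSE,
                                       progress = FALSE)
  out <- list(counts = read1("counts.csv"), assays = read1("assays.csv"),
              samples = read1("samples.csv"))
  if (file.exists(file.path(dir, "truth.csv")))
    out$truth <- read1("truth.csv")
  out
}
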