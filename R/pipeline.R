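#' Reduce raw counting series to decay-corrected activities
#'
#' One row per sample: the ingrowth fit ([fit_ingrowth_series()]) with
#' yield correction, decay correction of the estimate to the reference
#' date, the per-sample detection limit, and flags. Samples whose series
#' departs from the 90Y growth curve (goodness-of-fit p < 0.05) are
#' flagged, not dropped; per-row problems (missing counts, invalid
#' yield) are recorded in `note` and the run continues.
#'
#' @param counts Tibble `sample_id`, `t_hours`, `duration_min`,
#'   `gross_counts`.
#' @param samples Tibble `sample_id`, `ash_mass_g`, `chemical_yield`,
#'   `thickness_mg_cm2`, `separation_date`, `status`, ...
#' @param calib An [assay_calibration()] object.
#' @param constants A [nuclide_constants()] object.
#' @param gof_alpha Flagging threshold for the ingrowth fit (default
#'   0.05).
#' @return Tibble: `sample_id`, `activity_mbq_sep`, `se_mbq`, `gof_p`,
#'   `gof_flag`, `activity_mbq_ref`, `below_detection`,
#'   `detection_limit_mbq`, `status`, `note`.
#' @export
run_reduce <- function(counts, samples, calib = assay_calibration(),
                       constants = nuclide_constants(), gof_alpha = 0.05) {
  counts <- as.data.frame(counts)
  samples <- as.data.frame(samples)
  if (nrow(counts) == 0) {
    warning("empty counts table: nothing to reduce")
    return(tibble::tibble(
      sample_id = character(), activity_mbq_sep = numeric(),
      se_mbq = numeric(), gof_p = numeric(), gof_flag = logical(),
      activity_mbq_ref = numeric(), below_detection = logical(),
      detection_limit_mbq = numeric(), status = character(),
      note = character()))
  }
  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    base <- tibble::tibble(
      sample_id = s$sample_id, activity_mbq_sep = NA_real_,
      se_mbq = NA_real_, gof_p = NA_real_, gof_flag = NA,
      activity_mbq_ref = NA_real_, below_detection = NA,
      detection_limit_mbq = NA_real_,
      status = s$status, note = NA_character_)
    if (!identical(s$status, "ok")) {
      out[[i]] <- base
      next
    }
    obs <- counts[counts$sample_id == s$sample_id, , drop = FALSE]
    res <- tryCatch({
      if (nrow(obs) == 0) stop("no counting series for sample")
      if (is.na(s$chemical_yield) ||
          !(s$chemical_yield > 0 && s$chemical_yield <= 1))
        stop("chemical yield outside (0, 1]")
      fit <- fit_ingrowth_series(obs, s$thickness_mg_cm2,
                                 yield = s$chemical_yield,
                                 calib = calib, constants = constants,
                                 separation_date = s$separation_date)
      dl <- detection_limit(calib,
                            count_duration = calib$background_duration,
                            yield = s$chemical_yield,
                            ash_mass_g = s$ash_mass_g,
                            ca_fraction = NULL)
      base$activity_mbq_sep <- 1000 * fit$activity_at_separation
      base$se_mbq <- 1000 * fit$standard_error
      base$gof_p <- fit$goodness_of_fit_p
      base$gof_flag <- fit$goodness_of_fit_p < gof_alpha
      base$activity_mbq_ref <- 1000 * fit$activity_at_reference
      base$detection_limit_mbq <- dl$activity_limit_mbq
      base$below_detection <- fit$below_detection ||
        base$activity_mbq_sep < dl$activity_limit_mbq
      base
    }, error = function(e) {
      base$note <- conditionMessage(e)
      base
    })
    out[[i]] <- res
  }
  dplyr::bind_rows(out)
}

#' Determine stable Sr and Ca composition from assay records
#'
#' Per sample and element, the three ICP replicates are reduced
#' separately (a standard-addition line for Sr, a calibration-curve
#' inverse prediction for Ca) and summarised as a triplicate mean and
#' SD, mirroring how such assays are averaged in practice.
#'
#' @param assays Tibble `sample_id`, `element`, `method`, `point_conc`
#'   (NA marks the unknown-sample readings of a calibration-curve
#'   assay), `intensity`, `replicate`.
#' @param lab Laboratory geometry (a `scenario_config$lab` list or any
#'   list with `dilution_factor`, `solution_volume_l`, `ash_mass_g`).
#' @return Tibble: `sample_id`, `sr_ug_g_mean`, `sr_ug_g_sd`,
#'   `ca_frac_mean`, `ca_frac_sd`, `note`.
#' @export
run_compose <- function(assays, lab = default_scenario()$lab) {
  assays <- as.data.frame(assays)
  ids <- unique(assays$sample_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    a <- assays[assays$sample_id == ids[i], , drop = FALSE]
    row <- tibble::tibble(sample_id = ids[i],
                          sr_ug_g_mean = NA_real_, sr_ug_g_sd = NA_real_,
                          ca_frac_mean = NA_real_, ca_frac_sd = NA_real_,
                          note = NA_character_)
    res <- tryCatch({
      sr <- a[a$element == "Sr", ]
      ca <- a[a$element == "Ca", ]
      sr_est <- vapply(sort(unique(sr$replicate)), function(r) {
        d <- sr[sr$replicate == r, ]
        standard_addition_concentration(
          d$point_conc, d$intensity,
          dilution_factor = lab$dilution_factor,
          solution_volume_l = lab$solution_volume_l,
          ash_mass_g = lab$ash_mass_g)$conc_ug_per_g
      }, numeric(1))
      ca_est <- vapply(sort(unique(ca$replicate)), function(r) {
        d <- ca[ca$replicate == r, ]
        std <- d[!is.na(d$point_conc), ]
        smp <- d[is.na(d$point_conc), ]
        cc <- calibration_curve_concentration(
          std$point_conc, std$intensity, mean(smp$intensity),
          dilution_factor = lab$dilution_factor,
          solution_volume_l = lab$solution_volume_l,
          ash_mass_g = lab$ash_mass_g)
        cc$conc_ug_per_g / 1e6            # ug/g ash -> g Ca per g ash
      }, numeric(1))
      s_sr <- triplicate_summary(sr_est)
      s_ca <- triplicate_summary(ca_est)
      row$sr_ug_g_mean <- s_sr$mean
      row$sr_ug_g_sd <- s_sr$sd
      row$ca_frac_mean <- s_ca$mean
      row$ca_frac_sd <- s_ca$sd
      if (!s_sr$complete || !s_ca$complete)
        row$note <- "incomplete triplicate"
      row
    }, error = function(e) {
      row$note <- conditionMessage(e)
      row
    })
    out[[i]] <- res
  }
  dplyr::bind_rows(out)
}

#' Normalise reduced activities to Ca and stable Sr
#'
#' Joins the reduced activities with the per-sample composition and the
#' sample metadata and computes both reporting scales
#' ([normalize_activity()]), recomputing the per-g-Ca detection limit
#' with the sample's own measured Ca fraction.
#'
#' @param reduced Output of [run_reduce()].
#' @param composition Output of [run_compose()].
#' @param samples The sample metadata table.
#' @return Tibble with identification, lab fields, composition,
#'   `activity_conc_mbq_g_ca`, `specific_activity_bq_g_sr`,
#'   `detection_limit_mbq_g_ca`, flags and `status`.
#' @export
run_normalize <- function(reduced, composition, samples) {
  d <- dplyr::left_join(tibble::as_tibble(samples),
                        tibble::as_tibble(reduced),
                        by = c("sample_id", "status"))
  d <- dplyr::left_join(d, tibble::as_tibble(composition), by = "sample_id")
  usable <- d$status == "ok" & !is.na(d$activity_mbq_ref) &
    !is.na(d$sr_ug_g_mean) & !is.na(d$ca_frac_mean)
  d$activity_conc_mbq_g_ca <- NA_real_
  d$specific_activity_bq_g_sr <- NA_real_
  d$detection_limit_mbq_g_ca <- NA_real_
  if (any(usable)) {
    norm <- normalize_activity(pmax(d$activity_mbq_ref[usable], 0),
                               d$ash_mass_g[usable],
                               d$sr_ug_g_mean[usable],
                               d$ca_frac_mean[usable])
    d$activity_conc_mbq_g_ca[usable] <- norm$activity_conc_mbq_g_ca
    d$specific_activity_bq_g_sr[usable] <- norm$specific_activity_bq_g_sr
    d$detection_limit_mbq_g_ca[usable] <- d$detection_limit_mbq[usable] /
      (d$ash_mass_g[usable] * d$ca_frac_mean[usable])
  }
  d
}

#' Rank tests over a normalised tooth table
#'
#' Runs the tie-corrected Kruskal-Wallis test of a response against a
#' grouping factor after pooling tooth positions into developmental
#' classes ([group_teeth()]). Degenerate inputs (fewer than two
#' non-empty groups) yield an NA row flagged `not_applicable` rather
#' than an error.
#'
#' @param normalized Output of [run_normalize()] (or any table with
#'   `area`, `tooth_class`, `status` and the response column).
#' @param response Response column name.
#' @param by `"area"` or `"tooth_group"`.
#' @return One-row tibble: `factor`, `response`, `groups`, `N`,
#'   `statistic`, `df`, `p`, `note`.
#' @export
run_rank_test <- function(normalized, response = "activity_conc_mbq_g_ca",
                          by = c("area", "tooth_group")) {
  by <- match.arg(by)
  res <- tryCatch({
    g <- group_teeth(normalized, by = by, value_col = response)
    kw <- kruskal_wallis(g$value, g$label)
    tibble::tibble(factor = by, response = response,
                   groups = length(kw$group_sizes),
                   N = sum(kw$group_sizes),
                   statistic = kw$statistic, df = kw$df, p = kw$p,
                   note = NA_character_)
  }, error = function(e) {
    tibble::tibble(factor = by, response = response, groups = NA_integer_,
                   N = NA_integer_, statistic = NA_real_, df = NA_integer_,
                   p = NA_real_, note = paste("not_applicable:",
                                              conditionMessage(e)))
  })
  res
}

#' Summary report of a processed study
#'
#' Per-area and per-class summaries (mean +/- sd of both reporting
#' scales), the area and tooth-class rank tests, and the rank
#' correlations of the per-tooth values against the soil deposition of
#' the areas. All numbers are taken from the normalised table; nothing
#' is recomputed upstream of it.
#'
#' @param normalized Output of [run_normalize()].
#' @param soil Soil table ([area_soil_table()] by default).
#' @return List with `area_summary`, `class_summary`, `tests`,
#'   `soil_correlations`.
#' @export
run_report <- function(normalized, soil = area_soil_table()) {
  d <- tibble::as_tibble(normalized)
  ok <- d[d$status == "ok" & !is.na(d$activity_conc_mbq_g_ca), ]
  map <- c(DM1 = "DM", DM2 = "DM", DM3 = "DM", M1 = "M", M2 = "M",
           M3 = "M", P1 = "P", P2 = "P", P3 = "P")
  ok$tooth_group <- unname(map[as.character(ok$tooth_class)])
  area_summary <- dplyr::summarise(
    dplyr::group_by(ok, area),
    n = dplyr::n(),
    activity_conc_mean = mean(activity_conc_mbq_g_ca),
    activity_conc_sd = stats::sd(activity_conc_mbq_g_ca),
    specific_mean = mean(specific_activity_bq_g_sr),
    specific_sd = stats::sd(specific_activity_bq_g_sr),
    .groups = "drop")
  class_summary <- dplyr::summarise(
    dplyr::group_by(ok, area, tooth_group),
    n = dplyr::n(),
    activity_conc_mean = mean(activity_conc_mbq_g_ca),
    specific_mean = mean(specific_activity_bq_g_sr),
    .groups = "drop")
  tests <- dplyr::bind_rows(
    run_rank_test(d, "activity_conc_mbq_g_ca", by = "area"),
    run_rank_test(d, "specific_activity_bq_g_sr", by = "area"),
    run_rank_test(d, "activity_conc_mbq_g_ca", by = "tooth_group"),
    run_rank_test(d, "specific_activity_bq_g_sr", by = "tooth_group"))
  soil_at <- soil$soil_sr90_bq_m2[match(ok$area, soil$area)]
  soil_correlations <- tryCatch({
    s1 <- spearman_rank(ok$activity_conc_mbq_g_ca, soil_at)
    s2 <- spearman_rank(ok$specific_activity_bq_g_sr, soil_at)
    tibble::tibble(
      response = c("activity_conc_mbq_g_ca", "specific_activity_bq_g_sr"),
      rho = c(s1$rho, s2$rho), p = c(s1$p, s2$p),
      p_one_sided = c(s1$p_one_sided, s2$p_one_sided),
      n = c(s1$n, s2$n))
  }, error = function(e) {
    tibble::tibble(response = character(), rho = numeric(), p = numeric(),
                   p_one_sided = numeric(), n = integer())
  })
  list(area_summary = area_summary, class_summary = class_summary,
       tests = tests, soil_correlations = soil_correlations)
}

#' Run the whole chain on one simulated study
#'
#' simulate -> reduce -> compose -> normalize -> report, returning every
#' intermediate stage. Convenience wrapper used by the analysis scripts
#' and the acceptance checks.
#'
#' @param scenario A `scenario_config` list.
#' @param seed Integer seed for the simulation.
#' @param noise Passed to [simulate_lab()].
#' @return List with `truth`, `lab`, `reduced`, `composition`,
#'   `normalized`, `report`.
#' @export
run_pipeline <- function(scenario = default_scenario(), seed = 1,
                         noise = "poisson") {
  truth <- simulate_truth(scenario, seed = seed)
  lab <- simulate_lab(truth, scenario, noise = noise)
  calib <- scenario_calibration(scenario)
  reduced <- run_reduce(lab$counts, lab$samples, calib)
  composition <- run_compose(lab$assays, scenario$lab)
  normalized <- run_normalize(reduced, composition, lab$samples)
  list(truth = truth, lab = lab, reduced = reduced,
       composition = composition, normalized = normalized,
       report = run_report(normalized))
}

#' Manifest of a run directory
#'
#' MD5 digests and sizes of the files a pipeline stage wrote; rerunning
#' with an identical scenario and seed reproduces identical digests.
#'
#' @param dir Directory of CSV outputs.
#' @param seed Seed recorded alongside the digests.
#' @return Tibble `file`, `md5`, `bytes`, `seed`.
#' @export
run_manifest <- function(dir, seed = NA_integer_) {
  files <- sort(list.files(dir, full.names = TRUE))
  tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files),
    seed = seed
  )
}
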