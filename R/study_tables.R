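#' The eight study animals
#'
#' Herd description of the cattle study: four young animals (8 months
#' old at the accident) from the high- and low-contamination areas, two
#' adults from the low area, and two controls from an uncontaminated
#' area 250 km away. Ages are in months; areas are coded H, L, C.
#'
#' @return Tibble with `animal_id`, `area`, `birth_date`,
#'   `age_accident_months`, `age_sampling_months`.
#' @export
cattle_table <- function() {
  tibble::tibble(
    animal_id = c("H-young-1", "H-young-2", "L-young-1", "L-young-2",
                  "L-adult-1", "L-adult-2", "control-1", "control-2"),
    area = c("H", "H", "L", "L", "L", "L", "C", "C"),
    birth_date = as.Date(c("2010-06-16", "2010-07-08", "2010-07-08",
                           "2010-07-08", "2009-04-19", "2006-11-27",
                           "2011-01-09", "2011-01-28")),
    age_accident_months = c(8, 8, 8, 8, 22, 51, 2, 1),
    age_sampling_months = c(25, 24, 17, 16, 30, 60, 24, 24)
  )
}

#' Stable Sr concentrations in incinerated tooth samples
#'
#' The per-tooth stable strontium concentrations (triplicate mean and
#' SD, ug per g ash) of the eight study animals. Missing teeth carry a
#' status: `fallen_out` (the tooth was gone by sampling, mostly the
#' adults' deciduous molars) or `separation_failed` (the Sr chemistry
#' did not succeed).
#'
#' @return Long tibble with `animal_id`, `area`, `tooth_class`,
#'   `sr_ug_g`, `sr_sd`, `status`.
#' @export
stable_sr_table <- function() {
  classes <- c("DM1", "DM2", "DM3", "M1", "M2", "M3", "P1", "P2", "P3")
  row <- function(id, vals, sds, status) {
    tibble::tibble(animal_id = id, tooth_class = classes,
                   sr_ug_g = vals, sr_sd = sds, status = status)
  }
  ok <- rep("ok", 9)
  out <- dplyr::bind_rows(
    row("H-young-1",
        c(113, 106, 94.2, 122, 136, 157, 169, 153, 189),
        c(1.4, 0.6, 0.6, 0.7, 0.4, 0.3, 0.4, 0.4, 0.3), ok),
    row("H-young-2",
        c(193, 194, 206, 206, 238, 248, 255, 239, 241),
        c(0.3, 1.0, 0.7, 1.2, 0.4, 0.4, 0.2, 0.4, 0.1), ok),
    row("L-young-1",
        c(141, 128, 114, 122, 125, 159, 184, 166, 173),
        c(1.8, 0.3, 1.1, 0.4, 0.8, 0.5, 0.5, 0.4, 1.2), ok),
    row("L-young-2",
        c(NA, 133, 139, 147, 158, 214, NA, 165, NA),
        c(NA, 0.3, 0.5, 0.5, 1.3, 0.6, NA, 0.8, NA),
        c("separation_failed", "ok", "ok", "ok", "ok", "ok",
          "separation_failed", "ok", "separation_failed")),
    row("L-adult-1",
        c(NA, NA, 181, 187, 205, 204, 211, 213, 197),
        c(NA, NA, 0.3, 4.1, 0.7, 0.2, 0.7, 1.0, 1.3),
        c("fallen_out", "fallen_out", rep("ok", 7))),
    row("L-adult-2",
        c(NA, NA, NA, 190, 155, 126, 137, 134, 121),
        c(NA, NA, NA, 0.7, 0.4, 0.9, 1.9, 0.8, 1.1),
        c(rep("fallen_out", 3), rep("ok", 6))),
    row("control-1",
        c(NA, NA, 157, 145, 166, 163, 163, 163, 158),
        c(NA, NA, 0.1, 0.8, 0.4, 0.5, 0.2, 0.4, 0.1),
        c("separation_failed", "fallen_out", rep("ok", 7))),
    row("control-2",
        c(214, 212, 233, 209, 184, 201, 201, 190, 181),
        c(0.3, 0.7, 1.2, 0.6, 0.5, 0.5, 0.4, 0.8, 0.6), ok)
  )
  herd <- cattle_table()
  out$area <- herd$area[match(out$animal_id, herd$animal_id)]
  out[, c("animal_id", "area", "tooth_class", "sr_ug_g", "sr_sd", "status")]
}

#' Soil 90Sr deposition of the three study areas
#'
#' Area H, 5 km west of the plant inside the evacuation zone; area L,
#' 16 km south-west; control area C, 250 km north. Values are Bq m^-2.
#'
#' @return Tibble with `area`, `soil_sr90_bq_m2` (area mean),
#'   `soil_min`, `soil_max`.
#' @export
area_soil_table <- function() {
  tibble::tibble(
    area = c("H", "L", "C"),
    soil_sr90_bq_m2 = c(738, 195, 96),
    soil_min = c(94, 39, 95),
    soil_max = c(1500, 380, 99)
  )
}
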