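## Loaders for the packaged calibration tables transcribed from the
## published retrospective cohort summaries (per-arm, per-outcome-stratum
## Me [Q1; Q3] entries, tropism symbols, demographics, operated-level
## frequencies).  Entries the source tables do not print (preoperative
## ODI/VAS levels, disc height-loss fraction) are shipped with
## source = "assumed" and documented in the methods vignette.

calib_file <- function(name) {
  path <- system.file("extdata", name, package = "lumbartriage")
  if (!nzchar(path)) stop("calibration file not found: ", name)
  path
}

#' Load the per-stratum clinical calibration table
#'
#' @return data.frame keyed by (arm, stratum, variable) with me/q1/q3,
#'   optional clamps, an integer flag and the provenance column `source`
#' @export
stratum_calibration <- function() {
  utils::read.csv(calib_file("stratum_calibration.csv"),
                  stringsAsFactors = FALSE)
}

#' Load the per-stratum tropism symbols
#' @return data.frame with arm, stratum, symbol ("+", "-", "+/-")
#' @export
stratum_tropism <- function() {
  utils::read.csv(calib_file("stratum_tropism.csv"), stringsAsFactors = FALSE)
}

#' Load demographics calibration (age, BMI) per arm and cohort
#' @return data.frame like [stratum_calibration()]
#' @export
demographics_calibration <- function() {
  utils::read.csv(calib_file("demographics_calibration.csv"),
                  stringsAsFactors = FALSE)
}

#' Load sex counts per arm and cohort
#' @return data.frame with arm, cohort, male, female
#' @export
sex_counts <- function() {
  utils::read.csv(calib_file("sex_counts.csv"), stringsAsFactors = FALSE)
}

#' Load operated-level frequencies per arm and cohort
#' @return data.frame with arm, cohort, level, count
#' @export
level_frequencies <- function() {
  utils::read.csv(calib_file("level_frequencies.csv"), stringsAsFactors = FALSE)
}

#' Look up one calibration entry as a quartile spec
#'
#' @param arm one of [treatment_arms()] or "ALL" for shared entries
#' @param stratum "good", "poor", or "all"
#' @param variable row name in the calibration table
#' @param table optionally a preloaded [stratum_calibration()] data.frame
#' @return a [quartile_spec()]
#' @export
calibration_spec <- function(arm, stratum, variable,
                             table = stratum_calibration()) {
  row <- table[table$arm == arm & table$stratum == stratum &
                 table$variable == variable, ]
  if (nrow(row) != 1L)
    stop(sprintf("no calibration entry for (%s, %s, %s)",
                 arm, stratum, variable))
  quartile_spec(row$me, row$q1, row$q3, lower = row$lower, upper = row$upper,
                integer_valued = row$integer_valued)
}

#' Printed retrospective stratum sizes
#'
#' Good/poor outcome counts of the retrospective arms (35/7, 64/15, 62/13).
#'
#' @return data.frame with arm, n_good, n_poor
#' @export
stratum_sizes <- function() {
  data.frame(arm = c("TDR", "MI_TLIF", "O_TLIF"),
             n_good = c(35L, 64L, 62L),
             n_poor = c(7L, 15L, 13L))
}

#' The six per-stratum preoperative median profiles
#'
#' Each retrospective arm-by-outcome stratum's preoperative medians assembled
#' into a [segment_profile()]: the canonical concordance fixtures.  Tropism
#' is mapped "+" to present, "-" to absent, "+/-" to unknown.
#'
#' @return named list of six profiles, names like "TDR.good"
#' @export
median_profiles <- function() {
  cal <- stratum_calibration()
  tro <- stratum_tropism()
  out <- list()
  for (arm in treatment_arms()) {
    for (stratum in c("good", "poor")) {
      get <- function(v) calibration_spec(arm, stratum, v, cal)$me
      sym <- tro$symbol[tro$arm == arm & tro$stratum == stratum]
      out[[paste(arm, stratum, sep = ".")]] <- segment_profile(
        level = "L4-L5",
        linear_translation = get("linear_translation"),
        sagittal_angulation = get("sagittal_angulation"),
        facet_angle = get("facet_angle"),
        tropism_present = switch(sym, "+" = TRUE, "-" = FALSE, NA),
        pfirrmann = get("pfirrmann"),
        fujiwara = get("fujiwara"),
        adc = get("adc"),
        ivd_height = get("ivd_height"),
        height_loss_fraction = 0.5,
        general_lordosis = get("general_lordosis")
      )
    }
  }
  out
}
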