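#' @keywords internal
"_PACKAGE"

## Scales and enumerations used throughout the package.

#' Lumbar segment levels recognised by the checklist
#' @export
segment_levels <- function() {
  c("L2-L3", "L3-L4", "L4-L5", "L5-S1", "L5-L6", "L6-S1")
}

#' Treatment arms
#' @export
treatment_arms <- function() c("TDR", "MI_TLIF", "O_TLIF")

.roman_grades <- c("I", "II", "III", "IV", "V")

#' Convert Roman-numeral degeneration grades to integers
#'
#' Checklist files carry Pfirrmann (I-V) and Fujiwara (I-IV) grades as Roman
#' numerals; internally the package works with integers.
#'
#' @param x character vector of Roman numerals (or integers, passed through)
#' @return integer vector; NA where unparseable
#' @export
roman_to_grade <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  x <- toupper(trimws(as.character(x)))
  out <- match(x, .roman_grades)
  as.integer(out)
}

#' Convert integer grades to Roman numerals
#' @param g integer vector in 1..5
#' @return character vector
#' @export
grade_to_roman <- function(g) {
  g <- as.integer(g)
  out <- rep(NA_character_, length(g))
  ok <- !is.na(g) & g >= 1L & g <= 5L
  out[ok] <- .roman_grades[g[ok]]
  out
}

#' Construct a lumbar segment profile
#'
#' One lumbar segment's preoperative biometric and radiological parameters:
#' the input vector of the triage algorithm.  Continuous instability measures
#' (linear translation on functional radiographs, sagittal flexion-extension
#' angulation, facet joint angle), degeneration measures (Pfirrmann disc grade,
#' Fujiwara facet grade, apparent diffusion coefficient of the disc), disc
#' height and its loss relative to the superjacent disc, and overall lumbar
#' lordosis.
#'
#' @param level segment level, one of [segment_levels()]
#' @param linear_translation anterior-posterior vertebral slip, mm, >= 0
#' @param sagittal_angulation flexion-extension segmental mobility, degrees,
#'   >= 0 (the same measure is sometimes called sagittal range of motion)
#' @param facet_angle facet joint angle, degrees, in (0, 180)
#' @param tropism_present facet tropism: TRUE, FALSE, or NA (unknown)
#' @param pfirrmann disc degeneration grade, integer 1..5 or Roman "I".."V"
#' @param fujiwara facet degeneration grade, integer 1..4 or Roman "I".."IV"
#' @param adc apparent diffusion coefficient of the disc, s/mm^2, > 0; lower
#'   values indicate more advanced disc degeneration
#' @param ivd_height intervertebral disc height, mm, > 0
#' @param height_loss_fraction disc height loss relative to the superjacent
#'   disc, dimensionless in [0, 1]
#' @param general_lordosis overall lumbar lordosis, degrees
#' @return an object of class `segment_profile` (a named list)
#' @seealso [validate_profile()], [eligibility_gate()], [classify()]
#' @export
#' @examples
#' p <- segment_profile(linear_translation = 2, sagittal_angulation = 4,
#'                      facet_angle = 50, pfirrmann = "II", fujiwara = "I",
#'                      adc = 1540, height_loss_fraction = 0.5)
#' validate_profile(p)
segment_profile <- function(level = "L4-L5",
                            linear_translation,
                            sagittal_angulation,
                            facet_angle,
                            tropism_present = NA,
                            pfirrmann,
                            fujiwara,
                            adc,
                            ivd_height = 10,
                            height_loss_fraction = 0.5,
                            general_lordosis = 32) {
  p <- list(
    level = as.character(level),
    linear_translation = as.numeric(linear_translation),
    sagittal_angulation = as.numeric(sagittal_angulation),
    facet_angle = as.numeric(facet_angle),
    tropism_present = as.logical(tropism_present),
    pfirrmann = roman_to_grade(pfirrmann),
    fujiwara = roman_to_grade(fujiwara),
    adc = as.numeric(adc),
    ivd_height = as.numeric(ivd_height),
    height_loss_fraction = as.numeric(height_loss_fraction),
    general_lordosis = as.numeric(general_lordosis)
  )
  structure(p, class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat("<segment_profile>", x$level, "\n")
  cat(sprintf("  translation %.1f mm | sagittal %.1f deg | facet %.1f deg | tropism %s\n",
              x$linear_translation, x$sagittal_angulation, x$facet_angle,
              ifelse(is.na(x$tropism_present), "unknown",
                     ifelse(x$tropism_present, "present", "absent"))))
  cat(sprintf("  Pfirrmann %s | Fujiwara %s | ADC %.0f s/mm2 | height %.1f mm (loss %.2f)\n",
              grade_to_roman(x$pfirrmann), grade_to_roman(x$fujiwara),
              x$adc, x$ivd_height, x$height_loss_fraction))
  invisible(x)
}

#' Validate a segment profile
#'
#' Checks every field of a [segment_profile()] against its scale and bounds.
#' Violations are returned as data, not raised: the function is total on any
#' finite (or non-finite) input and never throws.
#'
#' @param profile a `segment_profile`
#' @return character vector of violation messages, each naming the offending
#'   field; `character(0)` when the profile is valid
#' @export
validate_profile <- function(profile) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(profile$level %in% segment_levels(),
      sprintf("level: '%s' not one of %s", profile$level,
              paste(segment_levels(), collapse = ", ")))
  num_ok <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
  chk(num_ok(profile$linear_translation) && profile$linear_translation >= 0,
      "linear_translation: must be finite and >= 0 mm")
  chk(num_ok(profile$sagittal_angulation) && profile$sagittal_angulation >= 0,
      "sagittal_angulation: must be finite and >= 0 degrees")
  chk(num_ok(profile$facet_angle) && profile$facet_angle > 0 &&
        profile$facet_angle < 180,
      "facet_angle: must lie strictly between 0 and 180 degrees")
  chk(length(profile$pfirrmann) == 1L && !is.na(profile$pfirrmann) &&
        profile$pfirrmann %in% 1:5,
      "pfirrmann: grade must be I..V")
  chk(length(profile$fujiwara) == 1L && !is.na(profile$fujiwara) &&
        profile$fujiwara %in% 1:4,
      "fujiwara: grade must be I..IV")
  chk(num_ok(profile$adc) && profile$adc > 0,
      "adc: must be a positive diffusion coefficient (s/mm2)")
  chk(num_ok(profile$ivd_height) && profile$ivd_height > 0,
      "ivd_height: must be > 0 mm")
  chk(num_ok(profile$height_loss_fraction) &&
        profile$height_loss_fraction >= 0 && profile$height_loss_fraction <= 1,
      "height_loss_fraction: must lie in [0, 1]")
  chk(num_ok(profile$general_lordosis),
      "general_lordosis: must be finite (degrees)")
  v
}

#' Disc height loss relative to the superjacent disc
#'
#' Helper to express two measured disc heights as the loss fraction the
#' eligibility window is defined on.
#'
#' @param height_mm height of the index disc, mm
#' @param superjacent_mm height of the superjacent disc, mm, > 0
#' @return loss fraction `1 - height_mm / superjacent_mm`, floored at 0
#' @export
height_loss_fraction <- function(height_mm, superjacent_mm) {
  stopifnot(superjacent_mm > 0, height_mm >= 0)
  pmax(0, 1 - height_mm / superjacent_mm)
}

#' Disc-height eligibility gate
#'
#' Candidates enter the triage algorithm only when the index disc has lost
#' more than one third but no more than two thirds of the superjacent disc's
#' height: below the window the degeneration is too mild to operate, above it
#' the collapse is beyond the algorithm's remit.  Both ends are treated as
#' closed.
#'
#' @param profile a valid `segment_profile`
#' @param config a [rule_config()]
#' @return list with `eligible` (logical) and `reasons` (character, empty when
#'   eligible)
#' @export
eligibility_gate <- function(profile, config = rule_config()) {
  stop_if_invalid(profile)
  h <- profile$height_loss_fraction
  lo <- config$height_loss_window[1]
  hi <- config$height_loss_window[2]
  reasons <- character(0)
  if (h < lo)
    reasons <- sprintf("height_loss_fraction %.3f below %s of the superjacent disc", h, "1/3")
  if (h > hi)
    reasons <- sprintf("height_loss_fraction %.3f above %s of the superjacent disc", h, "2/3")
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

stop_if_invalid <- function(profile) {
  v <- validate_profile(profile)
  if (length(v))
    stop("invalid segment profile: ", paste(v, collapse = "; "), call. = FALSE)
  invisible(TRUE)
}

#' Construct a patient record
#'
#' A segment profile plus demographics and, optionally, the arm the patient
#' actually received and the labelled outcome stratum.
#'
#' @param id patient identifier
#' @param age years, > 0
#' @param sex "male" or "female"
#' @param bmi body mass index, kg/m^2, > 0
#' @param profile a [segment_profile()]
#' @param received_arm optional, one of [treatment_arms()]
#' @param outcome_label optional, "good" or "poor"
#' @param outcomes optional list of outcome records (see
#'   [generate_trajectories()])
#' @return object of class `patient_record`
#' @export
patient_record <- function(id, age, sex, bmi, profile,
                           received_arm = NA_character_,
                           outcome_label = NA_character_,
                           outcomes = list()) {
  stopifnot(age > 0, bmi > 0, sex %in% c("male", "female"))
  if (!is.na(received_arm)) stopifnot(received_arm %in% treatment_arms())
  if (!is.na(outcome_label)) stopifnot(outcome_label %in% c("good", "poor"))
  structure(list(id = as.character(id), age = as.numeric(age), sex = sex,
                 bmi = as.numeric(bmi), profile = profile,
                 received_arm = received_arm, outcome_label = outcome_label,
                 outcomes = outcomes),
            class = "patient_record")
}
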