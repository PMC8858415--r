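## Crisp two-stage triage: biomechanical instability family first, then the
## degeneration-driven arm within the family.

criterion_vote <- function(criterion, value, band, rationale) {
  list(criterion = criterion, value = value, band = band,
       rationale = rationale)
}

#' Biomechanical instability family of a segment
#'
#' Stage 1 of the triage: the instability triad.  Each of translation above
#' 4 mm, sagittal angulation of 6 degrees or more, and a facet angle of
#' 60 degrees or more casts a "rigid" vote; the family is rigid when at least
#' two of the three vote rigid (a majority over an odd triad, so no ties are
#' possible).
#'
#' @param profile a valid [segment_profile()]
#' @param config a [rule_config()]
#' @return list with `family` ("dynamic" or "rigid"), `rigid_votes` (0..3)
#'   and the named logical triad `votes`
#' @export
instability_family <- function(profile, config = rule_config()) {
  stop_if_invalid(profile)
  votes <- c(
    translation = profile$linear_translation > config$translation_max_tdr,
    sagittal = profile$sagittal_angulation >= config$sagittal_min_rigid,
    facet = profile$facet_angle >= config$facet_min_rigid
  )
  n_rigid <- sum(votes)
  list(family = if (n_rigid >= 2) "rigid" else "dynamic",
       rigid_votes = n_rigid, votes = votes)
}

#' ADC band of a disc
#'
#' Bands the apparent diffusion coefficient by the three published clauses:
#' at least 1240 s/mm^2 is compatible with disc replacement, below
#' 950 s/mm^2 favours open fusion, between 950 and 1150 favours the
#' minimally invasive fusion.  The gap [1150, 1240) satisfies no clause and
#' is reported as "neutral" rather than silently assigned.
#'
#' @param adc apparent diffusion coefficient, s/mm^2, > 0
#' @param config a [rule_config()]
#' @return one of "TDR_compatible", "MI", "O", "neutral"
#' @export
adc_band <- function(adc, config = rule_config()) {
  if (!is.numeric(adc) || !is.finite(adc) || adc <= 0)
    stop("adc must be a positive finite diffusion coefficient")
  if (adc >= config$adc_min_tdr) "TDR_compatible"
  else if (adc < config$adc_max_o) "O"
  else if (adc < config$adc_max_mi) "MI"
  else "neutral"
}

#' Pfirrmann disc-degeneration vote
#'
#' Grades I-II are compatible with disc replacement, III votes MI, V votes
#' open fusion.  Grade IV lies in both rigid bands (III-IV for MI, IV-V for
#' open) and is reported as an explicit MI/O tie.
#'
#' @param grade Pfirrmann grade, integer 1..5 or Roman numeral
#' @param config a [rule_config()]
#' @return one of "TDR_compatible", "MI", "O", "tie_MI_O"
#' @export
pfirrmann_vote <- function(grade, config = rule_config()) {
  g <- roman_to_grade(grade)
  if (is.na(g) || !(g %in% 1:5)) stop("pfirrmann grade must be I..V")
  in_mi <- g %in% config$pfirrmann_mi_band
  in_o <- g %in% config$pfirrmann_o_band
  if (g <= config$pfirrmann_tdr_max) "TDR_compatible"
  else if (in_mi && in_o) "tie_MI_O"
  else if (in_mi) "MI"
  else "O"
}

#' Fujiwara facet-degeneration vote
#'
#' Grade I is compatible with disc replacement, III votes MI, IV votes open
#' fusion.  Grade II lies in both the TDR and MI bands: it never blocks disc
#' replacement, and within the rigid family it counts as an MI vote.
#'
#' @param grade Fujiwara grade, integer 1..4 or Roman numeral
#' @param config a [rule_config()]
#' @param family optional family context ("dynamic" or "rigid") used to
#'   resolve the grade-II overlap; with no context the overlap is reported as
#'   "TDR_or_MI"
#' @return one of "TDR_compatible", "MI", "O", "TDR_or_MI"
#' @export
fujiwara_vote <- function(grade, config = rule_config(), family = NULL) {
  g <- roman_to_grade(grade)
  if (is.na(g) || !(g %in% 1:4)) stop("fujiwara grade must be I..IV")
  if (g == config$fujiwara_o_grade) return("O")
  in_tdr <- g <= config$fujiwara_tdr_max
  in_mi <- g %in% config$fujiwara_mi_band
  if (in_tdr && in_mi) {
    if (is.null(family)) "TDR_or_MI"
    else if (family == "rigid") "MI" else "TDR_compatible"
  } else if (in_tdr) "TDR_compatible"
  else "MI"
}

#' Facet tropism vote
#'
#' Under the default "prose" polarity absent tropism favours the minimally
#' invasive fusion and present tropism the open fusion; the "table" polarity
#' inverts the mapping.  Unknown tropism contributes nothing, and tropism
#' never affects disc-replacement eligibility.
#'
#' @param tropism_present TRUE, FALSE, or NA (unknown)
#' @param config a [rule_config()]
#' @return one of "MI", "O", "neutral"
#' @export
tropism_vote <- function(tropism_present, config = rule_config()) {
  if (is.na(tropism_present)) return("neutral")
  prose <- identical(config$tropism_polarity, "prose")
  if (tropism_present) {
    if (prose) "O" else "MI"
  } else {
    if (prose) "MI" else "O"
  }
}

#' Disc replacement eligibility
#'
#' All disc-replacement conditions are conjunctive, exactly as the clinical
#' rule is worded: translation at most 4 mm, sagittal angulation below
#' 6 degrees, facet angle below 60 degrees (each triad criterion
#' individually, which implies a dynamic family), Pfirrmann at most II,
#' Fujiwara at most II, and an ADC of at least 1240 s/mm^2.  Tropism is
#' ignored.
#'
#' @param profile a valid [segment_profile()]
#' @param config a [rule_config()]
#' @return list with `eligible` and the named logical vector `criteria`
#' @export
tdr_eligibility <- function(profile, config = rule_config()) {
  fam <- instability_family(profile, config)
  criteria <- c(
    translation = !fam$votes[["translation"]],
    sagittal = !fam$votes[["sagittal"]],
    facet = !fam$votes[["facet"]],
    pfirrmann = profile$pfirrmann <= config$pfirrmann_tdr_max,
    adc = adc_band(profile$adc, config) == "TDR_compatible",
    fujiwara = profile$fujiwara <= config$fujiwara_tdr_max
  )
  list(eligible = all(criteria), criteria = criteria)
}

#' Classify a segment profile into a surgical arm
#'
#' The crisp two-stage triage.  Stage 1 assigns the biomechanical family via
#' [instability_family()].  A dynamic segment is recommended for disc
#' replacement when all degeneration criteria are compatible
#' ([tdr_eligibility()]); dynamic biomechanics with rigid-type degeneration
#' is reported as INDETERMINATE rather than forced into an arm.  Within the
#' rigid family the MI and O votes of [adc_band()], [pfirrmann_vote()],
#' [fujiwara_vote()] and [tropism_vote()] are tallied; the Pfirrmann IV tie
#' contributes half a vote to each arm, neutral bands contribute nothing,
#' and an MI/O tie resolves toward the less invasive MI-TLIF.
#'
#' @param profile a valid [segment_profile()]
#' @param config a [rule_config()]
#' @return object of class `recommendation`: list with `arm`, `family`,
#'   `confidence` (winning vote share; 1 for TDR, 0 for INDETERMINATE),
#'   `votes` (per-criterion vote records covering the seven evaluated
#'   criteria) and `audit` (ordered fired-rule descriptions)
#' @export
#' @examples
#' p <- segment_profile(linear_translation = 2, sagittal_angulation = 4,
#'                      facet_angle = 50, pfirrmann = "II", fujiwara = "I",
#'                      adc = 1540)
#' classify(p)
classify <- function(profile, config = rule_config()) {
  stop_if_invalid(profile)
  fam <- instability_family(profile, config)
  family <- fam$family

  band_adc <- adc_band(profile$adc, config)
  band_pf <- pfirrmann_vote(profile$pfirrmann, config)
  band_fu <- fujiwara_vote(profile$fujiwara, config, family = family)
  band_tr <- tropism_vote(profile$tropism_present, config)

  triad_desc <- sprintf(
    "%s: %s (value %.5g, threshold %.5g)",
    names(fam$votes),
    ifelse(fam$votes, "rigid", "dynamic"),
    c(profile$linear_translation, profile$sagittal_angulation,
      profile$facet_angle),
    c(config$translation_max_tdr, config$sagittal_min_rigid,
      config$facet_min_rigid))

  votes <- list(
    criterion_vote("translation", profile$linear_translation,
                   ifelse(fam$votes[["translation"]], "rigid", "dynamic"),
                   triad_desc[1]),
    criterion_vote("sagittal", profile$sagittal_angulation,
                   ifelse(fam$votes[["sagittal"]], "rigid", "dynamic"),
                   triad_desc[2]),
    criterion_vote("facet", profile$facet_angle,
                   ifelse(fam$votes[["facet"]], "rigid", "dynamic"),
                   triad_desc[3]),
    criterion_vote("adc", profile$adc, band_adc,
                   sprintf("ADC %.5g s/mm2 -> %s", profile$adc, band_adc)),
    criterion_vote("pfirrmann", grade_to_roman(profile$pfirrmann), band_pf,
                   sprintf("Pfirrmann %s -> %s",
                           grade_to_roman(profile$pfirrmann), band_pf)),
    criterion_vote("fujiwara", grade_to_roman(profile$fujiwara), band_fu,
                   sprintf("Fujiwara %s -> %s (family %s)",
                           grade_to_roman(profile$fujiwara), band_fu, family)),
    criterion_vote("tropism", profile$tropism_present, band_tr,
                   sprintf("tropism %s -> %s",
                           ifelse(is.na(profile$tropism_present), "unknown",
                                  ifelse(profile$tropism_present, "present",
                                         "absent")),
                           band_tr))
  )
  audit <- vapply(votes, function(v) v$rationale, "")

  if (family == "dynamic") {
    elig <- tdr_eligibility(profile, config)
    if (elig$eligible) {
      arm <- "TDR"; confidence <- 1
      audit <- c(audit, "dynamic family; all disc-replacement criteria met -> TDR")
    } else {
      arm <- "INDETERMINATE"; confidence <- 0
      failed <- names(elig$criteria)[!elig$criteria]
      audit <- c(audit, sprintf(
        "dynamic family but rigid-type degeneration (%s) -> INDETERMINATE",
        paste(failed, collapse = ", ")))
    }
  } else {
    stage2 <- c(band_adc, band_pf, band_fu, band_tr)
    mi <- sum(stage2 == "MI") + 0.5 * sum(stage2 == "tie_MI_O")
    o <- sum(stage2 == "O") + 0.5 * sum(stage2 == "tie_MI_O")
    cast <- mi + o
    if (cast == 0) {
      arm <- config$tie_break; confidence <- 0
      audit <- c(audit, "rigid family; no MI/O votes cast -> tie-break arm")
    } else {
      arm <- if (mi > o) "MI_TLIF" else if (o > mi) "O_TLIF" else config$tie_break
      confidence <- max(mi, o) / cast
      audit <- c(audit, sprintf(
        "rigid family; MI votes %.1f vs O votes %.1f -> %s", mi, o, arm))
    }
  }

  structure(list(arm = arm, family = family, confidence = confidence,
                 votes = votes, audit = audit),
            class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("<recommendation> arm %s (family %s, confidence %.2f)\n",
              x$arm, x$family, x$confidence))
  for (a in x$audit) cat("  -", a, "\n")
  invisible(x)
}

#' Serialize a recommendation to JSON
#'
#' @param rec a `recommendation`
#' @return a length-one character JSON string
#' @export
recommendation_json <- function(rec) {
  jsonlite::toJSON(list(
    arm = rec$arm, family = rec$family, confidence = rec$confidence,
    votes = lapply(rec$votes, function(v)
      list(criterion = v$criterion, value = v$value, band = v$band,
           rationale = v$rationale)),
    audit = rec$audit
  ), auto_unbox = TRUE, digits = NA)
}

#' Scan a parameter for the decision boundary
#'
#' Varies one continuous profile parameter over a grid and returns the first
#' scanned value at which a predicate on the resulting recommendation flips
#' relative to its value at the start of the scan.  Under the crisp rules
#' every single-parameter predicate is monotone, so the flip point recovers
#' the configured threshold exactly.
#'
#' @param base_profile a valid [segment_profile()]
#' @param parameter name of the numeric profile field to scan
#' @param from,to,step scan grid (inclusive, ascending)
#' @param predicate function(recommendation) -> logical
#' @param config a [rule_config()]
#' Grid points at which the scanned profile fails validation (for example an
#' ADC of 0 at the bottom of an ascending ADC scan) are skipped.
#'
#' @return list with `value` (first scanned value where the predicate
#'   differs from its initial state), `previous` (the last evaluated grid
#'   point before the flip) and `initial` (the predicate at the first valid
#'   grid point)
#' @export
probe_boundary <- function(base_profile, parameter, from, to, step = 1,
                           predicate, config = rule_config()) {
  stopifnot(parameter %in% names(base_profile), to >= from, step > 0)
  grid <- seq(from, to, by = step)
  state0 <- NULL
  prev <- NA_real_
  for (v in grid) {
    p <- base_profile
    p[[parameter]] <- v
    if (length(validate_profile(p))) next
    res <- isTRUE(predicate(classify(p, config)))
    if (is.null(state0)) {
      state0 <- res
    } else if (res != state0) {
      return(list(value = v, previous = prev, initial = state0))
    }
    prev <- v
  }
  stop(sprintf("no boundary in range: predicate constant (%s) over [%s, %s]",
               state0, from, to), call. = FALSE)
}
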