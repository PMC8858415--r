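## Fuzzy-inference variant of the crisp triage.  The published system is
## described only as "fuzzy logic" over the same thresholds; the membership
## construction here is this package's own and is documented in the methods
## vignette.

## Linear transition around threshold t with half-width w: membership of the
## "x at least t" side.  w = 0 degenerates to the crisp inclusive indicator.
ramp_ge <- function(x, t, w) {
  if (w <= 0) return(as.numeric(x >= t))
  pmin(1, pmax(0, (x - (t - w)) / (2 * w)))
}

## Membership of "x below t" (exclusive at t in the crisp limit).
ramp_lt <- function(x, t, w) {
  if (w <= 0) return(as.numeric(x < t))
  1 - ramp_ge(x, t, w)
}

## Membership of "x at most t" (inclusive at t in the crisp limit).
ramp_le <- function(x, t, w) {
  if (w <= 0) return(as.numeric(x <= t))
  1 - ramp_ge(x, t, w)
}

#' Fuzzy criterion memberships for a profile
#'
#' Each crisp continuous threshold t is widened into a linear transition of
#' half-width `w = fuzzy_width_fraction * t`; at the threshold itself the
#' membership is 0.5, at t - w and t + w it saturates at 0 and 1.  Ordinal
#' criteria (Pfirrmann, Fujiwara, tropism) keep crisp 0/1 memberships: a
#' width proportional to a grade number has no meaning on an ordinal scale.
#'
#' @param profile a valid [segment_profile()]
#' @param config a [rule_config()]
#' @return named list of memberships in [0, 1]: `rigid` (triad memberships
#'   toward the rigid family), `tdr` (disc-replacement criterion
#'   memberships), `mi_support` and `o_support` (stage-2 arm support per
#'   criterion)
#' @export
fuzzy_memberships <- function(profile, config = rule_config()) {
  stop_if_invalid(profile)
  f <- config$fuzzy_width_fraction
  w <- function(t) f * t

  rigid <- c(
    translation = 1 - ramp_le(profile$linear_translation,
                              config$translation_max_tdr,
                              w(config$translation_max_tdr)),
    sagittal = ramp_ge(profile$sagittal_angulation, config$sagittal_min_rigid,
                       w(config$sagittal_min_rigid)),
    facet = ramp_ge(profile$facet_angle, config$facet_min_rigid,
                    w(config$facet_min_rigid))
  )

  adc_tdr <- ramp_ge(profile$adc, config$adc_min_tdr, w(config$adc_min_tdr))
  below_mi <- ramp_lt(profile$adc, config$adc_max_mi, w(config$adc_max_mi))
  below_o <- ramp_lt(profile$adc, config$adc_max_o, w(config$adc_max_o))

  tdr <- c(
    translation = 1 - rigid[["translation"]],
    sagittal = 1 - rigid[["sagittal"]],
    facet = 1 - rigid[["facet"]],
    adc = adc_tdr,
    pfirrmann = as.numeric(profile$pfirrmann <= config$pfirrmann_tdr_max),
    fujiwara = as.numeric(profile$fujiwara <= config$fujiwara_tdr_max)
  )

  pf_band <- pfirrmann_vote(profile$pfirrmann, config)
  fu_band <- fujiwara_vote(profile$fujiwara, config, family = "rigid")
  tr_band <- tropism_vote(profile$tropism_present, config)

  mi_support <- c(
    adc = below_mi * (1 - below_o),
    pfirrmann = switch(pf_band, MI = 1, tie_MI_O = 0.5, 0),
    fujiwara = as.numeric(fu_band == "MI"),
    tropism = as.numeric(tr_band == "MI")
  )
  o_support <- c(
    adc = below_o,
    pfirrmann = switch(pf_band, O = 1, tie_MI_O = 0.5, 0),
    fujiwara = as.numeric(fu_band == "O"),
    tropism = as.numeric(tr_band == "O")
  )

  list(rigid = rigid, tdr = tdr, mi_support = mi_support,
       o_support = o_support)
}

#' Fuzzy classification of a segment profile
#'
#' The fuzzy counterpart of [classify()].  The rigid-family degree is the
#' median of the three triad memberships (the continuous analogue of the
#' 2-of-3 majority).  In the dynamic regime the disc-replacement activation
#' is the minimum of its criterion memberships (the conjunction); in the
#' rigid regime MI and O activations are the normalised sums of their
#' criterion supports.  With `fuzzy_width_fraction = 0` the recommended arm
#' equals [classify()]'s for every profile.
#'
#' @param profile a valid [segment_profile()]
#' @param config a [rule_config()]; set `fuzzy_width_fraction` there
#' @return a `recommendation` whose `confidence` is the activation margin
#'   between the top two arms and which carries the membership table in
#'   `memberships`
#' @export
fuzzy_classify <- function(profile, config = rule_config()) {
  if (config$fuzzy_width_fraction < 0)
    stop("fuzzy_width_fraction must be >= 0")
  m <- fuzzy_memberships(profile, config)
  rigid_degree <- stats::median(m$rigid)

  audit <- c(
    sprintf("rigid-family degree %.3f (median of triad memberships %s)",
            rigid_degree, paste(sprintf("%.3f", m$rigid), collapse = "/"))
  )

  if (rigid_degree < 0.5) {
    family <- "dynamic"
    act_tdr <- min(m$tdr)
    arm <- if (act_tdr >= 0.5) "TDR" else "INDETERMINATE"
    confidence <- abs(act_tdr - (1 - act_tdr))
    audit <- c(audit, sprintf(
      "dynamic regime; TDR activation %.3f (min of criterion memberships) -> %s",
      act_tdr, arm))
  } else {
    family <- "rigid"
    mi <- sum(m$mi_support)
    o <- sum(m$o_support)
    if (mi + o == 0) {
      arm <- config$tie_break
      confidence <- 0
      audit <- c(audit, "rigid regime; no arm support -> tie-break arm")
    } else {
      act_mi <- mi / (mi + o)
      act_o <- o / (mi + o)
      arm <- if (act_mi > act_o) "MI_TLIF"
             else if (act_o > act_mi) "O_TLIF"
             else config$tie_break
      confidence <- abs(act_mi - act_o)
      audit <- c(audit, sprintf(
        "rigid regime; MI activation %.3f vs O activation %.3f -> %s",
        act_mi, act_o, arm))
    }
  }

  structure(list(arm = arm, family = family, confidence = confidence,
                 votes = list(), memberships = m, audit = audit),
            class = "recommendation")
}
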