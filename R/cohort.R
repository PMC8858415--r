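#' Cohort generation specification
#'
#' @param arm one of [treatment_arms()]
#' @param n_good,n_poor stratum sizes; defaults are the printed retrospective
#'   counts for the arm
#' @param cohort "retrospective" or "prospective"; prospective cohorts reuse
#'   the retrospective good-stratum profile calibration (no prospective
#'   profile table was published) with prospective demographics
#' @param seed integer seed making generation fully reproducible
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(arm, n_good = NULL, n_poor = NULL,
                        cohort = c("retrospective", "prospective"),
                        seed = 1L) {
  stopifnot(arm %in% treatment_arms())
  cohort <- match.arg(cohort)
  sizes <- stratum_sizes()
  row <- sizes[sizes$arm == arm, ]
  if (is.null(n_good)) n_good <- row$n_good
  if (is.null(n_poor)) n_poor <- row$n_poor
  stopifnot(n_good >= 0, n_poor >= 0)
  structure(list(arm = arm, n_good = as.integer(n_good),
                 n_poor = as.integer(n_poor), cohort = cohort,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# profile and outcome variables drawn per stratum
.stratum_vars <- c("odi_m24", "vas_back_m24", "vas_leg_m24",
                   "linear_translation", "sagittal_angulation",
                   "general_lordosis", "ivd_height", "adc", "facet_angle")

#' Generate a synthetic cohort
#'
#' Draws `n_good + n_poor` patient rows for one treatment arm.  Continuous
#' clinical variables and 24-month outcome scores come from two-piece
#' samplers fitted to the per-stratum quartile calibration; Pfirrmann and
#' Fujiwara grades from the ordinal sampler; tropism from the stratum's
#' printed symbol; age, BMI, sex and operated level from the demographics
#' tables.  Variables are sampled independently within a stratum — the
#' published tables carry no correlation structure — so generated profiles
#' reproduce marginals while stratum membership carries the dependence.
#'
#' @param spec a [cohort_spec()]
#' @return data.frame, one row per patient: id, age, sex, bmi, level,
#'   received_arm, outcome_label, the segment-profile columns, and the
#'   24-month odi/vas scores
#' @export
#' @examples
#' head(generate_cohort(cohort_spec("TDR", seed = 42)))
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_good + spec$n_poor
  cal <- stratum_calibration()
  tro <- stratum_tropism()

  empty <- data.frame(
    id = character(0), age = numeric(0), sex = character(0),
    bmi = numeric(0), level = character(0), received_arm = character(0),
    outcome_label = character(0), linear_translation = numeric(0),
    sagittal_angulation = numeric(0), facet_angle = numeric(0),
    tropism_present = logical(0), pfirrmann = integer(0),
    fujiwara = integer(0), adc = numeric(0), ivd_height = numeric(0),
    height_loss_fraction = numeric(0), general_lordosis = numeric(0),
    odi_m24 = numeric(0), vas_back_m24 = numeric(0),
    vas_leg_m24 = numeric(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  # profile strata: prospective cohorts are triaged patients, so their
  # preoperative profiles follow the good-outcome calibration
  profile_stratum <- function(stratum)
    if (spec$cohort == "prospective") "good" else stratum

  withr::with_seed(spec$seed, {
    rows <- lapply(c(rep("good", spec$n_good), rep("poor", spec$n_poor)),
                   function(stratum) {
      ps <- profile_stratum(stratum)
      vals <- vapply(.stratum_vars, function(v) {
        sample_continuous(fit_two_piece(calibration_spec(spec$arm, ps, v, cal)),
                          1L)
      }, numeric(1))
      # outcome scores always follow the patient's own outcome stratum
      if (ps != stratum) {
        for (v in c("odi_m24", "vas_back_m24", "vas_leg_m24"))
          vals[[v]] <- sample_continuous(
            fit_two_piece(calibration_spec(spec$arm, stratum, v, cal)), 1L)
      }
      sym <- tro$symbol[tro$arm == spec$arm & tro$stratum == ps]
      c(as.list(vals), list(
        stratum = stratum,
        pfirrmann = sample_ordinal(calibration_spec(spec$arm, ps, "pfirrmann",
                                                    cal), 1L),
        fujiwara = sample_ordinal(calibration_spec(spec$arm, ps, "fujiwara",
                                                   cal), 1L),
        tropism_present = sample_tropism(sym, 1L),
        height_loss_fraction = sample_continuous(
          fit_two_piece(calibration_spec("ALL", "all",
                                         "height_loss_fraction", cal)), 1L)
      ))
    })

    demo <- demographics_calibration()
    demo <- demo[demo$arm == spec$arm & demo$cohort == spec$cohort, ]
    names(demo)[names(demo) == "cohort"] <- "stratum"
    age_fit <- fit_two_piece(calibration_spec(spec$arm, spec$cohort, "age",
                                              demo))
    bmi_fit <- fit_two_piece(calibration_spec(spec$arm, spec$cohort, "bmi",
                                              demo))
    sex_tab <- sex_counts()
    sex_tab <- sex_tab[sex_tab$arm == spec$arm & sex_tab$cohort == spec$cohort, ]
    p_male <- sex_tab$male / (sex_tab$male + sex_tab$female)
    lev <- level_frequencies()
    lev <- lev[lev$arm == spec$arm & lev$cohort == spec$cohort, ]

    data.frame(
      id = sprintf("%s-%03d", spec$arm, seq_len(n)),
      age = sample_continuous(age_fit, n),
      sex = ifelse(runif(n) < p_male, "male", "female"),
      bmi = round(sample_continuous(bmi_fit, n), 1),
      level = sample(lev$level, n, replace = TRUE,
                     prob = lev$count / sum(lev$count)),
      received_arm = spec$arm,
      outcome_label = vapply(rows, function(r) r$stratum, ""),
      linear_translation = vapply(rows, `[[`, numeric(1), "linear_translation"),
      sagittal_angulation = vapply(rows, `[[`, numeric(1),
                                   "sagittal_angulation"),
      facet_angle = vapply(rows, `[[`, numeric(1), "facet_angle"),
      tropism_present = vapply(rows, `[[`, logical(1), "tropism_present"),
      pfirrmann = vapply(rows, `[[`, integer(1), "pfirrmann"),
      fujiwara = vapply(rows, `[[`, integer(1), "fujiwara"),
      adc = vapply(rows, `[[`, numeric(1), "adc"),
      ivd_height = vapply(rows, `[[`, numeric(1), "ivd_height"),
      height_loss_fraction = vapply(rows, `[[`, numeric(1),
                                    "height_loss_fraction"),
      general_lordosis = vapply(rows, `[[`, numeric(1), "general_lordosis"),
      odi_m24 = vapply(rows, `[[`, numeric(1), "odi_m24"),
      vas_back_m24 = vapply(rows, `[[`, numeric(1), "vas_back_m24"),
      vas_leg_m24 = vapply(rows, `[[`, numeric(1), "vas_leg_m24"),
      stringsAsFactors = FALSE)
  })
}

#' Convert a cohort row to a segment profile
#'
#' @param row one row of a [generate_cohort()] data.frame (or of a parsed
#'   checklist)
#' @return a [segment_profile()]
#' @export
row_to_profile <- function(row) {
  segment_profile(
    level = row$level,
    linear_translation = row$linear_translation,
    sagittal_angulation = row$sagittal_angulation,
    facet_angle = row$facet_angle,
    tropism_present = row$tropism_present,
    pfirrmann = row$pfirrmann,
    fujiwara = row$fujiwara,
    adc = row$adc,
    ivd_height = row$ivd_height,
    height_loss_fraction = row$height_loss_fraction,
    general_lordosis = row$general_lordosis)
}

#' Generate follow-up score trajectories for a cohort
#'
#' Interpolates each patient's ODI and VAS scores from a preoperative level
#' to the patient's calibrated 24-month endpoint at the follow-up schedule
#' (discharge taken at 0.5 months, then 3, 6 and 24 months) along an
#' exponential decay `end + (pre - end) * exp(-t / tau)` with a 3-month time
#' constant, plus additive Gaussian noise at the interior time points.  With
#' `noise_sd = 0` every trajectory is exactly monotone non-increasing
#' whenever the preoperative score exceeds the endpoint.
#'
#' @param cohort a [generate_cohort()] data.frame
#' @param seed integer seed
#' @param noise_sd standard deviation of the interior-point noise, score
#'   units
#' @param tau decay time constant, months
#' @return long data.frame: id, outcome_label, score ("odi", "vas_back",
#'   "vas_leg"), timepoint ("preop", "discharge", "m3", "m6", "m24"), months,
#'   value
#' @export
generate_trajectories <- function(cohort, seed = 1L, noise_sd = 1.5,
                                  tau = 3) {
  stopifnot(noise_sd >= 0, tau > 0)
  cal <- stratum_calibration()
  pre_fit <- lapply(c(odi = "odi_pre", vas_back = "vas_back_pre",
                      vas_leg = "vas_leg_pre"),
                    function(v) fit_two_piece(calibration_spec("ALL", "all", v,
                                                               cal)))
  months <- c(preop = 0, discharge = 0.5, m3 = 3, m6 = 6, m24 = 24)
  end_col <- c(odi = "odi_m24", vas_back = "vas_back_m24",
               vas_leg = "vas_leg_m24")

  withr::with_seed(seed, {
    out <- lapply(seq_len(nrow(cohort)), function(i) {
      per_score <- lapply(names(pre_fit), function(sc) {
        pre <- sample_continuous(pre_fit[[sc]], 1L)
        end <- cohort[[end_col[[sc]]]][i]
        mu <- end + (pre - end) * exp(-months / tau)
        mu[1] <- pre
        mu[length(mu)] <- end
        val <- mu
        interior <- seq(2, length(mu) - 1)
        val[interior] <- mu[interior] + rnorm(length(interior), 0, noise_sd)
        val <- pmin(100, pmax(0, round(val)))
        data.frame(id = cohort$id[i],
                   outcome_label = cohort$outcome_label[i],
                   score = sc, timepoint = names(months),
                   months = unname(months), value = val,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, per_score)
    })
    do.call(rbind, out)
  })
}
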