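#' Decision-rule configuration
#'
#' All thresholds of the triage algorithm in one place.  The defaults encode
#' the published clinical rules: dynamic fixation (TDR) requires linear
#' translation of at most 4 mm, sagittal mobility below 6 degrees and a facet
#' angle below 60 degrees, disc degeneration no worse than Pfirrmann II and
#' Fujiwara II, and a disc ADC of at least 1240 s/mm^2.  Rigid stabilisation
#' splits on degeneration: ADC below 1150 s/mm^2 with Pfirrmann III-IV and
#' Fujiwara II-III favours the minimally invasive fusion, ADC below
#' 950 s/mm^2 with Pfirrmann IV-V and Fujiwara IV favours open fusion.
#'
#' Boundary inclusivity follows the wording of the rules: "to a maximum of
#' 4 mm" keeps 4 mm TDR-compatible, "not less than 6" and "over 60" make 6
#' and 60 rigid-voting, "not less than 1240" keeps 1240 TDR-compatible, and
#' the 1150/950 ADC bounds are exclusive upper bounds.
#'
#' The source rules state tropism in two mutually inconsistent places: the
#' prose assigns absent tropism to the minimally invasive arm and present
#' tropism to the open arm, while the printed cohort table shows the opposite
#' symbols for the good-outcome strata.  `tropism_polarity` selects which
#' reading the engine uses; the default is the prose.
#'
#' @param translation_max_tdr mm; largest translation compatible with TDR
#'   (inclusive)
#' @param sagittal_min_rigid degrees; sagittal angulation at or above this
#'   votes rigid
#' @param facet_min_rigid degrees; facet angle at or above this votes rigid
#' @param adc_min_tdr s/mm^2; smallest ADC compatible with TDR (inclusive)
#' @param adc_max_mi s/mm^2; ADC strictly below this (and at least
#'   `adc_max_o`) votes MI-TLIF
#' @param adc_max_o s/mm^2; ADC strictly below this votes O-TLIF
#' @param pfirrmann_tdr_max highest Pfirrmann grade compatible with TDR
#' @param pfirrmann_mi_band Pfirrmann grades voting MI (grade 4 overlaps the
#'   open band and is treated as a tie)
#' @param pfirrmann_o_band Pfirrmann grades voting open fusion
#' @param fujiwara_tdr_max highest Fujiwara grade compatible with TDR
#' @param fujiwara_mi_band Fujiwara grades voting MI (grade 2 overlaps the
#'   TDR band)
#' @param fujiwara_o_grade Fujiwara grade voting open fusion
#' @param tropism_polarity "prose" (absent -> MI, present -> O) or "table"
#'   (inverted)
#' @param height_loss_window closed disc-height-loss eligibility window,
#'   fractions of the superjacent disc height
#' @param fuzzy_width_fraction half-width of the fuzzy transition around each
#'   continuous threshold, as a fraction of the threshold; 0 reproduces the
#'   crisp rules exactly
#' @param tie_break arm preferred when MI and O votes tie ("MI_TLIF", the
#'   less invasive option, by default)
#' @return object of class `rule_config`
#' @export
rule_config <- function(translation_max_tdr = 4,
                        sagittal_min_rigid = 6,
                        facet_min_rigid = 60,
                        adc_min_tdr = 1240,
                        adc_max_mi = 1150,
                        adc_max_o = 950,
                        pfirrmann_tdr_max = 2L,
                        pfirrmann_mi_band = c(3L, 4L),
                        pfirrmann_o_band = c(4L, 5L),
                        fujiwara_tdr_max = 2L,
                        fujiwara_mi_band = c(2L, 3L),
                        fujiwara_o_grade = 4L,
                        tropism_polarity = c("prose", "table"),
                        height_loss_window = c(1 / 3, 2 / 3),
                        fuzzy_width_fraction = 0.10,
                        tie_break = "MI_TLIF") {
  tropism_polarity <- match.arg(tropism_polarity)
  cfg <- list(translation_max_tdr = translation_max_tdr,
              sagittal_min_rigid = sagittal_min_rigid,
              facet_min_rigid = facet_min_rigid,
              adc_min_tdr = adc_min_tdr,
              adc_max_mi = adc_max_mi,
              adc_max_o = adc_max_o,
              pfirrmann_tdr_max = as.integer(pfirrmann_tdr_max),
              pfirrmann_mi_band = as.integer(pfirrmann_mi_band),
              pfirrmann_o_band = as.integer(pfirrmann_o_band),
              fujiwara_tdr_max = as.integer(fujiwara_tdr_max),
              fujiwara_mi_band = as.integer(fujiwara_mi_band),
              fujiwara_o_grade = as.integer(fujiwara_o_grade),
              tropism_polarity = tropism_polarity,
              height_loss_window = height_loss_window,
              fuzzy_width_fraction = fuzzy_width_fraction,
              tie_break = tie_break)
  if (!(cfg$adc_max_o < cfg$adc_max_mi && cfg$adc_max_mi < cfg$adc_min_tdr))
    stop("ADC thresholds must satisfy adc_max_o < adc_max_mi < adc_min_tdr")
  if (diff(cfg$height_loss_window) < 0)
    stop("height_loss_window must be ordered")
  if (cfg$fuzzy_width_fraction < 0)
    stop("fuzzy_width_fraction must be >= 0")
  structure(cfg, class = "rule_config")
}

#' @export
print.rule_config <- function(x, ...) {
  cat("<rule_config>\n")
  for (k in names(x)) {
    val <- x[[k]]
    cat(sprintf("  %-22s %s\n", k, paste(format(val), collapse = ", ")))
  }
  invisible(x)
}

#' Read a rule configuration from a file
#'
#' Flat key-value configuration: YAML when the yaml package is installed (or
#' the file ends in .yml/.yaml), otherwise `key: value` lines.  Keys are
#' [rule_config()] argument names; absent keys keep their defaults.
#'
#' @param path file path
#' @return a `rule_config`
#' @export
read_rule_config <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE)) {
    vals <- yaml::read_yaml(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    kv <- strsplit(lines, ":", fixed = TRUE)
    vals <- lapply(kv, function(p) {
      v <- trimws(paste(p[-1], collapse = ":"))
      num <- suppressWarnings(as.numeric(strsplit(v, "[,;]\\s*|\\s+")[[1]]))
      if (!anyNA(num)) num else v
    })
    names(vals) <- vapply(kv, function(p) trimws(p[1]), "")
  }
  known <- names(formals(rule_config))
  vals <- vals[names(vals) %in% known]
  do.call(rule_config, vals)
}
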