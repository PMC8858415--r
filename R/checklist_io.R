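## Electronic-checklist I/O: CSV/JSON reading with row-level validation,
## writing, and the programmatic surface behind the command-line tool.

.checklist_cols <- c("id", "age", "sex", "bmi", "level",
                     "linear_translation", "sagittal_angulation",
                     "facet_angle", "tropism_present", "pfirrmann",
                     "fujiwara", "adc", "ivd_height",
                     "height_loss_fraction", "general_lordosis")

#' Read an electronic checklist
#'
#' One row per patient; grades may be Roman numerals ("I".."V") and tropism
#' "present"/"absent"/"unknown" or logical.  Rows failing profile validation
#' are rejected individually — valid rows are kept — and each rejection
#' message cites the file line.
#'
#' @param path CSV or JSON file
#' @param format "csv" or "json"; guessed from the extension by default
#' @return list with `records` (validated data.frame, grades as integers)
#'   and `errors` (character vector, one entry per rejected row)
#' @export
read_checklist <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  stopifnot(file.exists(path))
  df <- if (format == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  unknown <- setdiff(names(df), c(.checklist_cols,
                                  "received_arm", "outcome_label",
                                  "odi_m24", "vas_back_m24", "vas_leg_m24"))
  if (length(unknown))
    stop("unknown checklist columns: ", paste(unknown, collapse = ", "))
  missing <- setdiff(.checklist_cols, names(df))
  if (length(missing))
    stop("missing checklist columns: ", paste(missing, collapse = ", "))

  df$pfirrmann <- roman_to_grade(df$pfirrmann)
  df$fujiwara <- roman_to_grade(df$fujiwara)
  if (is.character(df$tropism_present)) {
    df$tropism_present <- c(present = TRUE, absent = FALSE,
                            unknown = NA)[tolower(df$tropism_present)]
  }

  errors <- character(0)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    v <- tryCatch(validate_profile(row_to_profile(df[i, ])),
                  error = function(e) conditionMessage(e))
    if (length(v)) {
      # header is line 1 in CSV files
      line <- if (format == "csv") i + 1L else i
      errors <- c(errors, sprintf("line %d (id %s): %s", line, df$id[i],
                                  paste(v, collapse = "; ")))
    } else keep[i] <- TRUE
  }
  list(records = df[keep, , drop = FALSE], errors = errors)
}

#' Write an electronic checklist
#'
#' Inverse of [read_checklist()]: grades rendered as Roman numerals, tropism
#' as "present"/"absent"/"unknown", comma-separated UTF-8 CSV with a header
#' row and "." as the decimal separator (or JSON).
#'
#' @param records checklist data.frame (integer grades)
#' @param path output file
#' @param format "csv" or "json"
#' @return `path`, invisibly
#' @export
write_checklist <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  out <- records
  out$pfirrmann <- grade_to_roman(out$pfirrmann)
  out$fujiwara <- grade_to_roman(out$fujiwara)
  out$tropism_present <- ifelse(is.na(records$tropism_present), "unknown",
                                ifelse(records$tropism_present, "present",
                                       "absent"))
  if (format == "json") {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         digits = NA)
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

write_manifest <- function(path, command, config, inputs, outputs,
                           seed = NULL) {
  digest <- function(f)
    if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_
  manifest <- list(
    command = command,
    config = unclass(config),
    inputs = lapply(inputs, function(f) list(path = f, md5 = digest(f))),
    outputs = lapply(outputs, function(f) list(path = f, md5 = digest(f))),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Classify every patient in a checklist file
#'
#' Writes one JSON recommendation per line and a run manifest
#' (`<output>.manifest.json`), and prints per-arm summary counts.
#'
#' @param input checklist file (CSV or JSON)
#' @param output path of the JSON-lines recommendations file
#' @param config a [rule_config()]
#' @param mode "crisp" or "fuzzy"
#' @return invisible list with `counts`, `n_invalid` and `status` (0 when
#'   every row was valid)
#' @export
cli_classify <- function(input, output, config = rule_config(),
                         mode = c("crisp", "fuzzy")) {
  mode <- match.arg(mode)
  parsed <- read_checklist(input)
  recs <- parsed$records
  engine <- if (mode == "fuzzy") fuzzy_classify else classify
  lines <- character(0)
  arms <- character(0)
  for (i in seq_len(nrow(recs))) {
    rec <- engine(row_to_profile(recs[i, ]), config)
    arms <- c(arms, rec$arm)
    lines <- c(lines, as.character(jsonlite::toJSON(
      c(list(id = recs$id[i]), jsonlite::fromJSON(recommendation_json(rec))),
      auto_unbox = TRUE, digits = NA)))
  }
  writeLines(lines, output)
  write_manifest(paste0(output, ".manifest.json"), "classify", config,
                 inputs = list(input), outputs = list(output))
  counts <- table(factor(arms, levels = c(treatment_arms(), "INDETERMINATE")))
  if (!nrow(recs)) warning("no valid rows in input; empty output written")
  for (e in parsed$errors) message(e)
  message(sprintf("classified %d patients (%s): %s", nrow(recs), mode,
                  paste(sprintf("%s=%d", names(counts), counts),
                        collapse = ", ")))
  invisible(list(counts = counts, n_invalid = length(parsed$errors),
                 status = if (length(parsed$errors)) 1L else 0L))
}

#' Simulate a cohort to a checklist CSV
#'
#' @param arm one of [treatment_arms()]
#' @param output CSV path (a manifest is written next to it)
#' @param n_good,n_poor stratum sizes; defaults are the printed
#'   retrospective counts
#' @param seed integer seed; the same seed reproduces the file byte for byte
#' @param cohort "retrospective" or "prospective"
#' @return the cohort data.frame, invisibly
#' @export
cli_simulate <- function(arm, output, n_good = NULL, n_poor = NULL,
                         seed = 1L, cohort = "retrospective") {
  spec <- cohort_spec(arm, n_good, n_poor, cohort, seed)
  tab <- generate_cohort(spec)
  write_checklist(cbind(tab[.checklist_cols],
                        tab[c("received_arm", "outcome_label", "odi_m24",
                              "vas_back_m24", "vas_leg_m24")]),
                  output)
  write_manifest(paste0(output, ".manifest.json"), "simulate",
                 list(spec = unclass(spec)), inputs = list(),
                 outputs = list(output), seed = seed)
  invisible(tab)
}

#' Compare two cohort files
#'
#' @param path_a,path_b checklist CSVs (e.g. from [cli_simulate()])
#' @param variables columns to compare; both files must carry them
#' @param output base path; writes `<output>.csv` and `<output>.txt`
#' @return the [compare_cohorts()] report, invisibly
#' @export
cli_evaluate <- function(path_a, path_b, variables, output) {
  a <- read_checklist(path_a)$records
  b <- read_checklist(path_b)$records
  rep <- compare_cohorts(a, b, variables)
  utils::write.csv(rep, paste0(output, ".csv"), row.names = FALSE)
  writeLines(format_report(rep, basename(path_a), basename(path_b)),
             paste0(output, ".txt"))
  write_manifest(paste0(output, ".manifest.json"), "evaluate", list(),
                 inputs = list(path_a, path_b),
                 outputs = list(paste0(output, ".csv"),
                                paste0(output, ".txt")))
  invisible(rep)
}

#' Recover all configured decision thresholds by boundary probing
#'
#' Runs [probe_boundary()] over each continuous criterion on nominal
#' profiles and returns the recovered thresholds, which under the crisp
#' rules equal the configuration values exactly.
#'
#' @param config a [rule_config()]
#' @return named numeric vector: translation, sagittal, facet, adc_tdr,
#'   adc_mi, adc_o
#' @export
recover_thresholds <- function(config = rule_config()) {
  tdr_nominal <- segment_profile(
    linear_translation = 2, sagittal_angulation = 4, facet_angle = 50,
    pfirrmann = 2, fujiwara = 1, adc = 1540, height_loss_fraction = 0.5)

  adc_tdr <- probe_boundary(tdr_nominal, "adc", 1, 2000, 1,
                            function(r) r$arm == "TDR", config)$value
  translation <- probe_boundary(tdr_nominal, "linear_translation", 0, 20, 1,
                                function(r) r$arm == "TDR", config)$previous
  one_rigid_sag <- tdr_nominal
  one_rigid_sag$sagittal_angulation <- 8
  facet <- probe_boundary(one_rigid_sag, "facet_angle", 1, 120, 1,
                          function(r) r$family == "rigid", config)$value
  one_rigid_facet <- tdr_nominal
  one_rigid_facet$facet_angle <- 70
  sagittal <- probe_boundary(one_rigid_facet, "sagittal_angulation", 0, 20, 1,
                             function(r) r$family == "rigid", config)$value
  # ADC band edges, scanned directly on the banding operation
  adc_grid <- seq_len(2000)
  bands <- vapply(adc_grid, function(a) adc_band(a, config), "")
  adc_o <- adc_grid[match(TRUE, bands != "O")]
  adc_mi <- adc_grid[match(TRUE, !(bands %in% c("O", "MI")))]
  c(translation = translation, sagittal = sagittal, facet = facet,
    adc_tdr = adc_tdr, adc_mi = adc_mi, adc_o = adc_o)
}
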