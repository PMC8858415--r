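## Nonparametric comparison machinery: Me [Q1; Q3] summaries, Mann-Whitney,
## Wilcoxon signed rank, Pearson chi-square, and table-style cohort reports.

#' Median and quartiles of a sample
#'
#' Quantiles use the linear-interpolation definition (type 7), fixed for the
#' whole package.
#'
#' @param values numeric vector, at least one value
#' @return list with `me`, `q1`, `q3` and the rendered `label`
#'   ("Me [Q1; Q3]", integers rendered without decimals)
#' @export
#' @examples
#' quartile_summary(c(6, 6, 6, 8, 8))$label   # "6 [6; 8]"
quartile_summary <- function(values) {
  if (length(values) < 1L) stop("quartile_summary needs at least one value")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  fmt <- function(x) {
    if (all(values == round(values))) format(round(x))
    else format(signif(x, 4))
  }
  list(me = q[2], q1 = q[1], q3 = q[3],
       label = sprintf("%s [%s; %s]", fmt(q[2]), fmt(q[1]), fmt(q[3])))
}

test_result <- function(statistic, p_value, method, n1, n2 = NA_integer_) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n1 = n1, n2 = n2),
            class = "triage_test")
}

#' @export
print.triage_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (n1 = %s, n2 = %s)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples.  The U
#' statistic is computed from joint midranks.  The p-value uses the exact
#' permutation distribution when both samples are small
#' (`min(n1, n2) <= exact_max`) and tie-free, and otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y numeric samples, both nonempty
#' @param exact_max largest smaller-sample size for which the exact
#'   distribution is used (tie-free data only)
#' @return a `triage_test` with `statistic` = U for `x`
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- min(n1, n2) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                       alternative = "two.sided"))
  test_result(wt$statistic, wt$p.value,
              if (use_exact) "Mann-Whitney U (exact)"
              else "Mann-Whitney U (normal approx., tie + continuity corr.)",
              n1, n2)
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired comparison.  Zero differences are dropped (documented
#' convention); the p-value is exact for `<= exact_max` informative tie-free
#' pairs, otherwise the normal approximation with tie and continuity
#' correction is used.  When every difference is zero the test is vacuous:
#' p = 1 with a warning.
#'
#' @param before,after paired numeric vectors of equal length
#' @param exact_max largest informative-pair count for the exact branch
#' @return a `triage_test` with `statistic` = V (sum of positive ranks)
#' @export
wilcoxon_signed_rank <- function(before, after, exact_max = 12L) {
  if (length(before) != length(after))
    stop("paired samples must have equal length")
  d <- after - before
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; test is vacuous")
    return(test_result(0, 1, "Wilcoxon signed rank (vacuous)",
                       length(before)))
  }
  ties <- anyDuplicated(abs(d)) > 0
  use_exact <- length(d) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = use_exact, correct = TRUE,
                       alternative = "two.sided"))
  test_result(wt$statistic, wt$p.value,
              if (use_exact) "Wilcoxon signed rank (exact)"
              else "Wilcoxon signed rank (normal approx.)",
              length(d))
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction by default (the variant that reproduces the
#' published sex-distribution p-value of 0.81 for the disc-replacement arm
#' from its printed counts); Yates' correction available by flag.
#'
#' @param a,b,c,d cell counts, row-wise: `rbind(c(a, b), c(c, d))`
#' @param yates apply the continuity correction
#' @return a `triage_test`
#' @export
#' @examples
#' chi_square_2x2(8, 3, 29, 13)$p_value   # ~0.81
chi_square_2x2 <- function(a, b, c, d, yates = FALSE) {
  m <- rbind(c(a, b), c(c, d))
  if (any(m < 0)) stop("counts must be nonnegative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(m, correct = yates))
  test_result(ct$statistic, ct$p.value,
              if (yates) "Pearson chi-square (Yates)" else "Pearson chi-square",
              sum(m[1, ]), sum(m[2, ]))
}

#' Compare two cohorts variable by variable
#'
#' Table-style report: continuous and ordinal variables get Me [Q1; Q3]
#' summaries and a Mann-Whitney comparison, binary (logical) variables get
#' counts (%) and an uncorrected Pearson chi-square.  Per-variable alpha is
#' 0.05 with no multiplicity correction by default, mirroring the published
#' analysis; Holm adjustment is available by flag.
#'
#' @param cohort_a,cohort_b data.frames sharing the requested columns
#' @param variables character vector of column names; rows keep this order
#' @param alpha significance level for the flag column
#' @param holm apply Holm adjustment across the report's p-values
#' @return data.frame of class `comparison_report`: variable, summary_a,
#'   summary_b, statistic, p_value, method, significant
#' @export
compare_cohorts <- function(cohort_a, cohort_b, variables, alpha = 0.05,
                            holm = FALSE) {
  missing_a <- setdiff(variables, names(cohort_a))
  missing_b <- setdiff(variables, names(cohort_b))
  if (length(missing_a) || length(missing_b))
    stop("variables absent from cohort: ",
         paste(unique(c(missing_a, missing_b)), collapse = ", "))
  empty <- data.frame(variable = character(0), summary_a = character(0),
                      summary_b = character(0), statistic = numeric(0),
                      p_value = numeric(0), method = character(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (!length(variables)) {
    class(empty) <- c("comparison_report", class(empty))
    return(empty)
  }
  rows <- lapply(variables, function(v) {
    xa <- cohort_a[[v]]; xb <- cohort_b[[v]]
    if (is.logical(xa)) {
      tt <- chi_square_2x2(sum(xa), sum(!xa), sum(xb), sum(!xb))
      sa <- sprintf("%d (%.1f)", sum(xa), 100 * mean(xa))
      sb <- sprintf("%d (%.1f)", sum(xb), 100 * mean(xb))
    } else {
      tt <- mann_whitney_u(xa, xb)
      sa <- quartile_summary(xa)$label
      sb <- quartile_summary(xb)$label
    }
    data.frame(variable = v, summary_a = sa, summary_b = sb,
               statistic = tt$statistic, p_value = tt$p_value,
               method = tt$method, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  p <- rep$p_value
  if (holm && length(p)) p <- stats::p.adjust(p, "holm")
  rep$significant <- p < alpha
  class(rep) <- c("comparison_report", class(rep))
  rep
}

#' Render a comparison report as aligned text
#'
#' @param report a [compare_cohorts()] report
#' @param label_a,label_b column headers for the two groups
#' @return character vector of lines (also printed)
#' @export
format_report <- function(report, label_a = "A", label_b = "B") {
  hdr <- sprintf("%-24s %-18s %-18s %8s", "Parameter", label_a, label_b, "p")
  lines <- c(hdr, strrep("-", nchar(hdr)))
  for (i in seq_len(nrow(report))) {
    lines <- c(lines, sprintf("%-24s %-18s %-18s %8.3g%s",
                              report$variable[i], report$summary_a[i],
                              report$summary_b[i], report$p_value[i],
                              if (report$significant[i]) " *" else ""))
  }
  lines
}

#' Concordance between engine recommendations and received arms
#'
#' Classifies every cohort row and compares the recommendation with the arm
#' the patient actually received.  Family-level concordance compares the
#' biomechanical family (disc replacement is the dynamic family, both
#' fusions are rigid); arm-level concordance compares the arm itself.
#' INDETERMINATE recommendations count as discordant on both levels.
#'
#' @param cohort data.frame with profile columns and `received_arm`
#' @param config a [rule_config()]
#' @param fuzzy use [fuzzy_classify()] instead of [classify()]
#' @return list with `family_concordance`, `arm_concordance`, `n`, and the
#'   per-patient data.frame `table`
#' @export
concordance <- function(cohort, config = rule_config(), fuzzy = FALSE) {
  if (!nrow(cohort)) stop("concordance is undefined for an empty cohort")
  if (!"received_arm" %in% names(cohort) || anyNA(cohort$received_arm))
    stop("every record needs a received_arm")
  fam_of <- function(arm) ifelse(arm == "TDR", "dynamic", "rigid")
  per <- lapply(seq_len(nrow(cohort)), function(i) {
    rec <- (if (fuzzy) fuzzy_classify else classify)(
      row_to_profile(cohort[i, ]), config)
    data.frame(id = cohort$id[i], received_arm = cohort$received_arm[i],
               recommended_arm = rec$arm, recommended_family = rec$family,
               family_match = rec$arm != "INDETERMINATE" &&
                 rec$family == fam_of(cohort$received_arm[i]),
               arm_match = rec$arm == cohort$received_arm[i],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per)
  list(family_concordance = mean(tab$family_match),
       arm_concordance = mean(tab$arm_match),
       n = nrow(tab), table = tab)
}
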