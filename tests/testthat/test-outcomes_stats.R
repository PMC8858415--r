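test_that("quartile summaries use linear interpolation and integer rendering", {
  s <- quartile_summary(c(6, 6, 6, 8, 8))
  expect_equal(c(s$me, s$q1, s$q3), c(6, 6, 8))
  expect_identical(s$label, "6 [6; 8]")
  expect_identical(quartile_summary(5)$label, "5 [5; 5]")
  expect_identical(quartile_summary(rep(3, 10))$label, "3 [3; 3]")
  expect_error(quartile_summary(numeric(0)), "at least one")
})

test_that("Mann-Whitney matches the enumeration oracle on every small rank pattern", {
  # every rank configuration for a grid of sample-size pairs
  for (sizes in list(c(3, 3), c(4, 4), c(3, 5), c(6, 5), c(6, 6))) {
    n1 <- sizes[1]; n2 <- sizes[2]
    subsets <- utils::combn(n1 + n2, n1)
    for (j in seq_len(ncol(subsets))) {
      x <- subsets[, j]
      y <- setdiff(seq_len(n1 + n2), x)
      got <- mann_whitney_u(x, y)
      expect_match(got$method, "exact")
      expect_equal(got$p_value, mw_enumeration_p(x, y), tolerance = 1e-10,
                   label = sprintf("n1=%d n2=%d config %d", n1, n2, j))
    }
  }
})

test_that("Mann-Whitney edge cases behave as documented", {
  # identical multisets: U = n1 n2 / 2, p ~ 1
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 4.5)
  expect_gt(r$p_value, 0.99)
  # complete separation: U = n1 n2, minimal attainable p
  r2 <- mann_whitney_u(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(r2$statistic, 16)
  expect_equal(r2$p_value, 2 / choose(8, 4), tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("U statistics of the two orientations sum to n1*n2 and p is symmetric", {
  withr::with_seed(31, {
    for (k in 1:30) {
      x <- rnorm(sample(3:15, 1)); y <- rnorm(sample(3:15, 1))
      a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
      expect_equal(a$statistic + b$statistic, length(x) * length(y))
      expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    }
  })
})

test_that("Wilcoxon signed rank matches the sign-enumeration oracle", {
  withr::with_seed(32, {
    for (n in 3:10) {
      for (k in 1:10) {
        d <- round(rnorm(n, 0.3, 1), 3)
        d <- d[d != 0]
        if (length(d) < 2 || anyDuplicated(abs(d))) next
        got <- wilcoxon_signed_rank(rep(0, length(d)), d)
        expect_match(got$method, "exact")
        expect_equal(got$p_value, wsr_enumeration_p(d), tolerance = 1e-10,
                     label = sprintf("n=%d rep=%d", n, k))
      }
    }
  })
})

test_that("Wilcoxon handles all-positive, vacuous and mismatched input", {
  before <- rep(0, 6); after <- 1:6
  r <- wilcoxon_signed_rank(before, after)
  expect_equal(r$p_value, 2 * (1 / 2^6), tolerance = 1e-12)
  expect_warning(r0 <- wilcoxon_signed_rank(1:4, 1:4), "vacuous")
  expect_equal(r0$p_value, 1)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("the chi-square reproduces the published sex comparison and is transpose-invariant", {
  r <- chi_square_2x2(8, 3, 29, 13)
  expect_equal(round(r$p_value, 2), 0.81)
  # hand Pearson value for the MI-arm sex counts
  r2 <- chi_square_2x2(16, 9, 57, 22)
  expect_equal(r2$statistic, 0.60, tolerance = 0.01)
  # transpose invariance
  expect_equal(chi_square_2x2(8, 29, 3, 13)$statistic, r$statistic,
               tolerance = 1e-12)
  # identical proportions: statistic 0, p 1
  r3 <- chi_square_2x2(10, 5, 20, 10)
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
  expect_error(chi_square_2x2(0, 0, 3, 4), "margins")
})

test_that("Mann-Whitney holds its size under the null", {
  f <- fit_two_piece(quartile_spec(4, 3, 5))
  withr::with_seed(33, {
    rejections <- vapply(seq_len(600), function(i) {
      mann_whitney_u(sample_continuous(f, 20),
                     sample_continuous(f, 20))$p_value < 0.05
    }, logical(1))
  })
  expect_gt(mean(rejections), 0.025)
  expect_lt(mean(rejections), 0.075)
})

test_that("compare_cohorts builds table-style rows in input order", {
  a <- generate_cohort(cohort_spec("TDR", n_good = 30, n_poor = 0, seed = 1))
  b <- generate_cohort(cohort_spec("TDR", n_good = 30, n_poor = 0, seed = 2))
  rep <- compare_cohorts(a, b, c("adc", "tropism_present", "odi_m24"))
  expect_identical(rep$variable, c("adc", "tropism_present", "odi_m24"))
  expect_match(rep$method[2], "chi-square")
  expect_match(rep$method[1], "Mann-Whitney")
  expect_identical(rep$significant, rep$p_value < 0.05)
  expect_equal(nrow(compare_cohorts(a, b, character(0))), 0L)
  expect_error(compare_cohorts(a, b, "nonexistent"), "nonexistent")
})

test_that("same-spec cohorts rarely flag; separated strata almost always do", {
  withr::with_seed(34, {
    null_flags <- vapply(1:60, function(i) {
      a <- generate_cohort(cohort_spec("TDR", n_good = 35, n_poor = 0,
                                       seed = 1000 + 2 * i))
      b <- generate_cohort(cohort_spec("TDR", n_good = 35, n_poor = 0,
                                       seed = 1001 + 2 * i))
      compare_cohorts(a, b, "adc")$significant
    }, logical(1))
    power_flags <- vapply(1:60, function(i) {
      co <- generate_cohort(cohort_spec("TDR", seed = 3000 + i))
      good <- co[co$outcome_label == "good", ]
      poor <- co[co$outcome_label == "poor", ]
      compare_cohorts(good, poor, "odi_m24")$significant
    }, logical(1))
  })
  expect_lt(mean(null_flags), 0.10)
  expect_gt(mean(power_flags), 0.5)
})

test_that("concordance scores the six fixtures 3/3 good and 0/3 poor", {
  mp <- median_profiles()
  to_row <- function(name, p) {
    arm <- sub("\\..*$", "", name)
    data.frame(id = name, received_arm = arm, level = p$level,
               linear_translation = p$linear_translation,
               sagittal_angulation = p$sagittal_angulation,
               facet_angle = p$facet_angle, tropism_present = p$tropism_present,
               pfirrmann = p$pfirrmann, fujiwara = p$fujiwara, adc = p$adc,
               ivd_height = p$ivd_height,
               height_loss_fraction = p$height_loss_fraction,
               general_lordosis = p$general_lordosis,
               stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, Map(to_row, names(mp), mp))
  good <- concordance(rows[grepl("good", rows$id), ])
  poor <- concordance(rows[grepl("poor", rows$id), ])
  expect_equal(good$family_concordance, 1)
  expect_equal(poor$family_concordance, 0)
  expect_error(concordance(rows[0, ]), "empty")
})
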