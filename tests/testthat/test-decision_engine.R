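test_that("instability triad majority assigns the family", {
  p <- tdr_nominal()
  expect_identical(instability_family(p)$family, "dynamic")
  expect_equal(instability_family(p)$rigid_votes, 0)

  p$linear_translation <- 7; p$sagittal_angulation <- 8; p$facet_angle <- 70
  fam <- instability_family(p)
  expect_identical(fam$family, "rigid")
  expect_equal(fam$rigid_votes, 3)

  # one rigid vote of three stays dynamic
  p2 <- tdr_nominal()
  p2$linear_translation <- 6; p2$sagittal_angulation <- 3; p2$facet_angle <- 52
  expect_identical(instability_family(p2)$family, "dynamic")
  expect_equal(instability_family(p2)$rigid_votes, 1)
})

test_that("ADC banding follows the three clauses and leaves the gap neutral", {
  cases <- list(list(adc = 1540, band = "TDR_compatible"),
                list(adc = 1240, band = "TDR_compatible"),
                list(adc = 1239.5, band = "neutral"),
                list(adc = 1200, band = "neutral"),
                list(adc = 1150, band = "neutral"),
                list(adc = 1149.5, band = "MI"),
                list(adc = 950, band = "MI"),
                list(adc = 949.5, band = "O"),
                list(adc = 670, band = "O"))
  for (cs in cases)
    expect_identical(adc_band(cs$adc), cs$band, info = cs$adc)
  expect_error(adc_band(-5), "positive")
})

test_that("Pfirrmann votes expose the grade-IV band overlap as a tie", {
  expect_identical(pfirrmann_vote("I"), "TDR_compatible")
  expect_identical(pfirrmann_vote("II"), "TDR_compatible")
  expect_identical(pfirrmann_vote("III"), "MI")
  expect_identical(pfirrmann_vote("IV"), "tie_MI_O")
  expect_identical(pfirrmann_vote("V"), "O")
  expect_error(pfirrmann_vote("VI"), "I..V")
})

test_that("Fujiwara grade II overlap resolves by family context", {
  expect_identical(fujiwara_vote("I"), "TDR_compatible")
  expect_identical(fujiwara_vote("II"), "TDR_or_MI")
  expect_identical(fujiwara_vote("II", family = "rigid"), "MI")
  expect_identical(fujiwara_vote("II", family = "dynamic"), "TDR_compatible")
  expect_identical(fujiwara_vote("III"), "MI")
  expect_identical(fujiwara_vote("IV"), "O")
  expect_error(fujiwara_vote(5), "I..IV")
})

test_that("tropism polarity maps prose and table readings symmetrically", {
  prose <- rule_config(tropism_polarity = "prose")
  tab <- rule_config(tropism_polarity = "table")
  expect_identical(tropism_vote(FALSE, prose), "MI")
  expect_identical(tropism_vote(TRUE, prose), "O")
  expect_identical(tropism_vote(FALSE, tab), "O")
  expect_identical(tropism_vote(TRUE, tab), "MI")
  expect_identical(tropism_vote(NA, prose), "neutral")
  expect_identical(tropism_vote(NA, tab), "neutral")
})

test_that("disc replacement eligibility is conjunctive over all criteria", {
  expect_true(tdr_eligibility(tdr_nominal())$eligible)
  edits <- list(list(adc = 1100, fails = "adc"),
                list(pfirrmann = 4L, fails = "pfirrmann"),
                list(fujiwara = 3L, fails = "fujiwara"),
                list(linear_translation = 5, fails = "translation"),
                list(sagittal_angulation = 6, fails = "sagittal"),
                list(facet_angle = 60, fails = "facet"))
  for (e in edits) {
    p <- tdr_nominal()
    p[setdiff(names(e), "fails")] <- e[setdiff(names(e), "fails")]
    elig <- tdr_eligibility(p)
    expect_false(elig$eligible, info = e$fails)
    expect_false(elig$criteria[[e$fails]])
  }
  # tropism never enters
  p <- tdr_nominal(); p$tropism_present <- TRUE
  expect_true(tdr_eligibility(p)$eligible)
})

test_that("classify reproduces hand-tallied stage-2 votes", {
  # rigid profile, Pfirrmann III (MI), ADC 1180 (neutral), Fujiwara III (MI),
  # tropism unknown: MI 2 vs O 0
  p <- segment_profile(linear_translation = 7, sagittal_angulation = 8,
                       facet_angle = 70, pfirrmann = "III", fujiwara = "III",
                       adc = 1180, tropism_present = NA)
  r <- classify(p)
  expect_identical(r$arm, "MI_TLIF")
  expect_identical(r$family, "rigid")
  expect_equal(r$confidence, 1)

  # Pfirrmann V, ADC 670, Fujiwara IV, tropism present: O 4 vs MI 0
  p2 <- segment_profile(linear_translation = 7, sagittal_angulation = 8,
                        facet_angle = 70, pfirrmann = "V", fujiwara = "IV",
                        adc = 670, tropism_present = TRUE)
  r2 <- classify(p2)
  expect_identical(r2$arm, "O_TLIF")
  expect_equal(r2$confidence, 1)

  # Pfirrmann IV splits 0.5/0.5; ADC 900 votes O, Fujiwara II votes MI,
  # tropism absent votes MI: MI 2.5 vs O 1.5
  p3 <- segment_profile(linear_translation = 7, sagittal_angulation = 8,
                        facet_angle = 70, pfirrmann = "IV", fujiwara = "II",
                        adc = 900, tropism_present = FALSE)
  r3 <- classify(p3)
  expect_identical(r3$arm, "MI_TLIF")
  expect_equal(r3$confidence, 2.5 / 4)
})

test_that("dynamic family with rigid-type degeneration is INDETERMINATE", {
  p <- tdr_nominal(); p$pfirrmann <- 4L
  r <- classify(p)
  expect_identical(r$arm, "INDETERMINATE")
  expect_identical(r$family, "dynamic")
  expect_equal(r$confidence, 0)
})

test_that("the audit trail covers all seven criteria and classify is deterministic", {
  withr::with_seed(11, {
    for (k in 1:25) {
      p <- random_profile()
      r1 <- classify(p); r2 <- classify(p)
      expect_identical(r1, r2)
      expect_setequal(vapply(r1$votes, `[[`, "", "criterion"),
                      c("translation", "sagittal", "facet", "adc",
                        "pfirrmann", "fujiwara", "tropism"))
      expect_gte(length(r1$audit), 8L)  # 7 criteria + decision line
    }
  })
})

test_that("stage-2 vote mass is conserved at four", {
  withr::with_seed(12, {
    for (k in 1:50) {
      p <- random_profile()
      fam <- instability_family(p)$family
      bands <- c(adc_band(p$adc), pfirrmann_vote(p$pfirrmann),
                 fujiwara_vote(p$fujiwara, family = fam),
                 tropism_vote(p$tropism_present))
      mi <- sum(bands == "MI") + 0.5 * sum(bands == "tie_MI_O")
      o <- sum(bands == "O") + 0.5 * sum(bands == "tie_MI_O")
      neutral <- sum(bands %in% c("neutral", "TDR_compatible", "TDR_or_MI"))
      expect_equal(mi + o + neutral, 4)
    }
  })
})

test_that("recommendations serialize to well-formed JSON", {
  j <- recommendation_json(classify(tdr_nominal()))
  parsed <- jsonlite::fromJSON(j)
  expect_identical(parsed$arm, "TDR")
  expect_identical(parsed$family, "dynamic")
  expect_equal(nrow(parsed$votes), 7L)
})

test_that("boundary probing flips exactly at the configured thresholds", {
  th <- recover_thresholds()
  expect_equal(unname(th), c(4, 6, 60, 1240, 1150, 950),
               tolerance = 0)
  # a custom config is recovered just as exactly
  cfg <- rule_config(translation_max_tdr = 3, adc_min_tdr = 1300,
                     sagittal_min_rigid = 7, facet_min_rigid = 65)
  th2 <- recover_thresholds(cfg)
  expect_equal(unname(th2[c("translation", "sagittal", "facet", "adc_tdr")]),
               c(3, 7, 65, 1300))
})

test_that("probe_boundary signals when the predicate never flips", {
  # a lone translation criterion cannot reach the 2-of-3 family majority
  expect_error(
    probe_boundary(tdr_nominal(), "linear_translation", 0, 20, 1,
                   function(r) r$family == "rigid"),
    "no boundary")
})
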