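Package: lumbartriage
Title: Rule-Based Surgical Triage for Single-Level Degenerative Lumbar Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clinical decision support engine that selects among total disc
    replacement (TDR), minimally invasive transforaminal lumbar interbody
    fusion (MI-TLIF), and open fusion (O-TLIF) for single-level degenerative
    lumbar disease from a preoperative electronic checklist of segment
    biometrics (linear translation, sagittal angulation, facet joint angle,
    facet tropism, Pfirrmann and Fujiwara degeneration grades, apparent
    diffusion coefficient, disc height loss).  Includes a fuzzy-inference
    variant of the crisp rules, a quantile-matched synthetic cohort generator
    calibrated to published median/quartile tables, and nonparametric
    group-comparison machinery (Mann-Whitney, Wilcoxon signed rank,
    chi-square) producing publication-style reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
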