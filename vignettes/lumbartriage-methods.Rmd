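---
title: "Rule-based surgical triage for the degenerative lumbar segment: model and methods"
author: "lumbartriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based surgical triage: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumbartriage)
```

## The clinical problem

Single-level degenerative lumbar disease admits three surgical strategies
with very different invasiveness: motion-preserving total disc replacement
(TDR), minimally invasive transforaminal interbody fusion (MI-TLIF), and
open fusion (O-TLIF).  Choosing among them from preoperative imaging is a
triage problem over a small set of segment biometrics: linear vertebral
translation (mm), sagittal flexion–extension angulation (degrees), facet
joint angle (degrees), facet tropism, Pfirrmann disc grade (I–V), Fujiwara
facet grade (I–IV), and the disc's apparent diffusion coefficient
(ADC, s/mm²), a diffusion-MRI hydration measure that falls as the disc
degenerates.  This package implements that triage as an auditable rule
engine, together with a synthetic-cohort generator calibrated to published
per-arm outcome tables and the nonparametric comparison machinery used to
evaluate such cohorts.

## The crisp engine

The engine is two-staged.

**Stage 1 — instability family.**  Three biomechanical criteria form the
instability triad: translation > 4 mm, sagittal angulation ≥ 6°, facet
angle ≥ 60°.  Each casts a "rigid" vote; the segment's family is *rigid*
when at least two of three vote rigid, otherwise *dynamic*.  A majority
over an odd triad is the minimal deterministic resolution of disagreeing
criteria, and it reproduces the family assignment of all six published
per-stratum median profiles (good strata map to the family of the arm the
stratum received, poor strata to the opposite family).

**Stage 2 — arm within the family.**  TDR eligibility is conjunctive over
every criterion exactly as the clinical rule is worded: translation ≤ 4 mm,
sagittal < 6°, facet < 60° (each individually, which is strictly stronger
than the family majority), Pfirrmann ≤ II, Fujiwara ≤ II, ADC ≥ 1240 s/mm².
A dynamic segment failing a degeneration criterion is reported
INDETERMINATE — the source rules never assign such patients, and the engine
does not invent a preference.  Within the rigid family, four criteria vote
MI or O: ADC in [950, 1150) votes MI and ADC < 950 votes O; Pfirrmann III
votes MI, V votes O, and IV — which the published bands place in *both*
rigid arms — contributes an explicit half-vote to each; Fujiwara II–III
votes MI and IV votes O; tropism votes by its configured polarity.  The
ADC gap [1150, 1240) satisfies no clause and is "neutral".  The arm is the
vote majority, ties resolving toward the less invasive MI-TLIF
(configurable), and the confidence is the winning vote share.  Every
recommendation carries a seven-criterion audit trail.

Boundary inclusivity follows the wording of the rules ("to a maximum of
4 mm" → 4 is TDR-compatible; "not less than 6°", "over 60°" → 6 and 60 vote
rigid; "not less than 1240" → 1240 is TDR-compatible; 1150 and 950 are
exclusive upper bounds).  `probe_boundary()` scans any continuous parameter
through `classify()` and recovers all six thresholds exactly
(`recover_thresholds()`).

**Tropism polarity.**  The source states tropism inconsistently: prose
assigns *absent* tropism to MI and *present* to O, while the printed
good-outcome strata show the opposite symbols.  Neither reading can be
reconciled with the other, so the polarity is a configuration switch
(`tropism_polarity`, default `"prose"`), not a silent patch.  Similarly,
the published good-outcome MI median ADC (1180) sits above the MI clause's
1150 bound, and the good-outcome O median grades (Pfirrmann III, Fujiwara
III) sit outside their clauses: the engine follows the prose clauses, and
these discrepancies surface honestly as sub-majority confidence on those
profiles rather than being absorbed into the thresholds.

**Eligibility gate.**  Candidates enter the algorithm when the index disc
has lost more than 1/3 but no more than 2/3 of the superjacent disc's
height.  The two bounds are stated in different places in the source and
their openness is unspecified; the window is treated as closed at both
ends, so a loss of exactly 1/3 or 2/3 is eligible.

## The fuzzy variant

The deployed clinical system is described only as using "fuzzy logic" over
the same thresholds; the membership construction here is this package's
own.  Each continuous threshold *t* is widened into a linear transition of
half-width *w* = `fuzzy_width_fraction` × *t* (default 0.10): membership is
0.5 at the threshold and saturates at *t* ± *w*.  Ordinal criteria keep
crisp 0/1 memberships — a width proportional to a grade number is not
meaningful on an ordinal scale — as does tropism.  The rigid-family degree
is the *median* of the three triad memberships, the continuous analogue of
the 2-of-3 majority; the TDR activation is the *minimum* of its criterion
memberships (the conjunction); MI and O activations are normalised sums of
their criterion supports.  Confidence is the activation margin between the
top two arms, so it shrinks smoothly as a profile approaches a threshold.
With `fuzzy_width_fraction = 0` every ramp degenerates to the crisp
indicator with the correct inclusivity, and the fuzzy arm equals the crisp
arm for every profile — a property the test suite checks over 1,000 random
profiles.

## The synthetic cohort generator

No patient-level data accompany the published tables; only per-stratum
medians and quartiles, Me [Q1; Q3], are printed.  The generator therefore
uses a **two-piece (split) normal**: location at the median, lower scale
σ_low = (Me − Q1)/z₀.₇₅ and upper scale σ_high = (Q3 − Me)/z₀.₇₅ with
z₀.₇₅ = qnorm(0.75) ≈ 0.6745.  This is the minimal model that reproduces
all three printed quantiles *exactly* in closed form, accommodates strongly
skewed entries such as ODI 6 [6; 8] (σ_low = 0: a half point-mass at the
median), and degenerates gracefully to a point mass.  Sampling is by
inverse transform; integer scores (ODI, VAS, grades) are rounded after
sampling and clamping to their scale happens last.  Ordinal grades are
sampled on their numeric axis and rounded, which preserves the printed
median grade in large samples.  Tropism symbols are mapped to prevalences
"+" → 0.9, "–" → 0.1, "+/–" → 0.5; the symbols are all the source prints,
so the 0.9/0.1 mapping is this package's documented choice.

Variables are sampled **independently within a stratum**: the published
tables carry no correlation structure, so generated cohorts reproduce
marginals while stratum membership (good/poor × arm) carries all the
dependence.  Passing tests on these cohorts therefore demonstrates
calibration of marginals and stratum separation, not joint realism of
individual profiles — a real patient's ADC and Pfirrmann grade are
correlated; synthetic ones are not.

Default stratum sizes are the printed retrospective counts (TDR 35/7,
MI-TLIF 64/15, O-TLIF 62/13); demographics (age, BMI, sex, operated level)
follow the printed per-arm distributions.  Prospective cohorts reuse the
retrospective good-stratum profile calibration — no prospective profile
table was published — with prospective demographics.  Two entries the
tables do not print are shipped with `source = "assumed"` in the packaged
calibration file and were fixed once: the disc height-loss fraction
(0.50 [0.45; 0.55], clamped inside the 1/3–2/3 gate: every study patient
passed inclusion) and preoperative ODI/VAS levels (ODI 52 [44; 60], back
VAS 70 [60; 80] mm, leg VAS 60 [50; 70] mm — typical severities for
surgical candidates in this population).

**Follow-up trajectories.**  The published score trajectories appear only
graphically, so `generate_trajectories()` interpolates each patient from
the preoperative level to their calibrated 24-month endpoint by exponential
decay, `end + (pre − end)·exp(−t/τ)` with τ = 3 months — most improvement
inside the first three months, near-plateau by six — evaluated at
discharge (0.5 months), 3, 6 and 24 months, with additive Gaussian noise
(SD 1.5 points) at the interior points.  With zero noise trajectories are
exactly monotone.  These trajectories are calibrated at their endpoints
only; their shape is an assumption, not a reproduction of the published
figures.

## Statistical machinery

Summaries are Me [Q1; Q3] with quantile type 7 (linear interpolation) fixed
package-wide; the source never states its software's convention.
`mann_whitney_u()` uses the exact permutation distribution when the smaller
sample has ≤ 8 observations and the data are tie-free, otherwise the normal
approximation with tie and continuity corrections; `wilcoxon_signed_rank()`
drops zero differences and is exact to 12 informative pairs.  The cutoffs
are conventional desk-scale choices; the exact branches are verified in the
tests against independent brute-force enumerations (all C(n₁+n₂, n₁) rank
assignments; all 2ⁿ sign vectors).  `chi_square_2x2()` is Pearson's χ²
*without* continuity correction by default — the variant that reproduces
the published sex-comparison p = 0.81 for the TDR arm from its printed
counts — with Yates' correction behind a flag.  Per-variable α = 0.05 with
no multiplicity correction mirrors the published analysis; Holm adjustment
is available but off by default.  The published follow-up endpoint
p-values cannot be recomputed without patient-level scores; the package
instead verifies, as power properties, that good and poor strata generated
at the printed sizes separate on the outcome scores and that same-spec
cohorts rarely flag.

## Worked example

```{r example}
profile <- segment_profile(linear_translation = 2, sagittal_angulation = 4,
                           facet_angle = 50, pfirrmann = "II",
                           fujiwara = "I", adc = 1540,
                           height_loss_fraction = 0.5)
classify(profile)
recover_thresholds()
```

```{r cohort}
cohort <- generate_cohort(cohort_spec("TDR", seed = 1))
good <- cohort[cohort$outcome_label == "good", ]
poor <- cohort[cohort$outcome_label == "poor", ]
compare_cohorts(good, poor, c("odi_m24", "vas_leg_m24", "adc"))
```

## Problem sizes and numerical choices

Calibration checks draw 20,000 samples per variable (sample medians land
within ±1 unit of integer-scale medians and ±2% of the ADC medians);
quantile-function identities are checked to machine precision; the
Mann-Whitney size check uses 2,000 null replicates at n = 20 vs 20; the
fuzzy/crisp degeneracy is property-tested over 1,000 random profiles;
power and null-rate checks on cohort comparison use 60 replicates at the
printed stratum sizes.  Ties in probing are impossible because the crisp
predicates are step functions of one scanned variable; grid points
producing invalid profiles (ADC 0, facet 0) are skipped.

## Known limitations

The engine encodes thresholds from a single-centre retrospective series;
it does not learn thresholds from data, handle multi-level disease, or
model sagittal-balance correction.  The generator reproduces printed
marginals only; the fuzzy construction beyond width-zero equivalence is
this package's design, not a reconstruction of the deployed system's
knowledge base; and the trajectory shape between calibrated endpoints is
assumed.
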