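---
title: "Modelling colonoscopy referral strategies after flexible sigmoidoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling colonoscopy referral strategies after flexible sigmoidoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fscreen)
```

## The screening problem

Flexible sigmoidoscopy (FS) examines the rectum, the sigmoid colon and — with
good insertion depth — the descending colon. Advanced neoplasia (AN; colorectal
cancer or advanced adenoma) located proximal to that reach can be found only
indirectly: a distal finding triggers referral to full colonoscopy, which is
then assumed to examine the whole colon. Which distal findings should trigger
referral is a policy choice; the four FS screening trials (UK, SCORE, NORCCAP,
US/PLCO) each used a different rule, and guidelines recommend yet others.

`fscreen` evaluates such rules on participant-level colonoscopy data by
simulating the two-stage process backwards: the colonoscopy record tells us
everything that is there; the FS reach assumption tells us what FS itself would
have seen; a referral rule applied to the FS-visible findings tells us who
would have received follow-up colonoscopy and therefore whose proximal lesions
would have been found.

## Model and assumptions

* **Perfect FS within reach.** FS detects exactly the lesions colonoscopy
  recorded at distal sites. No FS-specific miss rate is modelled.
* **Perfect follow-up colonoscopy.** A referred participant who attends has
  all remaining lesions detected. No colonoscopy miss rate is modelled.
* **Reach.** `descending_visualized` (the default: rectum, sigmoid, descending
  distal) or `sigmoid_only` (rectum and sigmoid distal), set per run.
* **Detection bookkeeping.** Endpoints are participant-level: CRC (any
  carcinoma), AA *as the most advanced finding* (so CRC carriers are excluded
  from the AA denominator), and any AN. Under the default
  `mode = "all_lesions"` a participant counts as detected for an endpoint only
  if *every* lesion of that endpoint class is detected. This is what makes the
  any-AN detected count smaller than the sum of the CRC and AA counts: a
  participant whose distal CRC is seen but whose proximal AA is not counts for
  CRC but not for any-AN. The alternative `mode = "any_lesion"` is provided
  because the defining sentence of a sensitivity analysis can be read either
  way; the `all_lesions` default is the reading consistent with the published
  per-endpoint counts.
* **Adherence.** By default every referred participant attends follow-up.
  With `adherence < 1`, attendance is an independent per-participant coin;
  `evaluate_strategies()` reports the closed-form expected counts (linear in
  the adherence probability, see `adherence_adjusted_gain()`) and, on request,
  seeded Monte-Carlo means across replicated attendance draws. Confidence
  intervals are only reported at full adherence, where counts are integers.

## Lesion classification and referral rules

An adenoma is advanced if it is at least 10 mm, has (tubulo-)villous
components, or shows high-grade dysplasia (HGD). Sizes are stored as integer
millimetres and the "≥ 1 cm" threshold is implemented as `size_mm >= 10`,
avoiding unit mixing and float comparisons. An adenoma with *missing* size and
no other advanced feature cannot be asserted advanced and is classified
non-advanced, with an audit warning. The HGD flag is honoured only on
adenomatous lesions: granting AN status to a dysplastic hyperplastic polyp
would break the containment of the histology-defined-AN rule within the
any-AN rule, and HGD outside adenomas does not define advanced neoplasia.

The twelve built-in rules (`builtin_strategies()`) follow the published
wordings, with two deliberately exposed interpretation knobs:

* The UK trial wrote "polyp or adenoma > 1 cm" while the other trials used
  "≥ 1 cm". The default implements `>= 10 mm` for consistency across rules;
  `uk_size_strict = TRUE` switches to a strict `> 10 mm` reading. The SCORE
  "polyp(s) > 5 mm" clause is strict.
* "Polyp" clauses include hyperplastic and other polyps; "adenoma" and
  "neoplasm" clauses do not. Count thresholds (≥ 3 adenomas, ≥ 2 neoplasms,
  ≥ 20 hyperplastic polyps above the rectum) count distal lesion rows — FS
  cannot count what it cannot see, so all counting is distal by construction.
* The PLCO score's published age bands end at "65–70: 3". Screening cohorts
  extend to age 79, so ages above 70 keep the maximal 3 points (the monotone
  extension; any AN-carrying man aged 55+ scores at least 1 + 1 + 3 ≥ 4, so
  the score always refers distal CRC at screening ages).

Referral predicates see only the distal summary (plus age and sex); a
property test mutates proximal lesions and asserts decisions are unchanged.

## Outcome measures

For each rule and stratum (men, women, both): the number of follow-up
colonoscopies; participants in whom a proximal AN would be detected; the
number of colonoscopies needed per proximal AN detected (NCN); the
incremental NCN against a reference rule (default: the most restrictive rule
examined, "≥ 2 neoplasms, ≥ 1 AN"), defined as additional colonoscopies per
additional proximal AN detected; per-endpoint sensitivity with exact
Clopper–Pearson 95% intervals (beta-quantile form, verified in tests against
`binom.test()`); and the negative predictive value — the probability that a
non-referred participant harbours no proximal lesion of the endpoint class.

Undefined ratios (NCN with nothing detected, incremental NCN with no
detection increment) are `NA` internally and an explicit `--` token in
rendered tables, never 0 or infinity. Rendered tables round half away from
zero — percentages to whole percent, ratios to one decimal — while all stored
values keep full precision. Two-path consistency (aggregated cells equal
re-aggregation of `screening_outcomes()` per-participant flags) is asserted
in the test suite.

`evaluate_counts()` recomputes every derived measure from an aggregate
strategy-level counts table. The package bundles such a table
(`kolossal_counts()`) for the KolosSal screening-colonoscopy cohort, from
which all headline published values (NCN 8.2, incremental NCN 11.8 and 17.8,
sensitivities 84/70/67%, the 77–90% interval, NPV 96.1%, the mixed-policy
yield of 183 proximal AN for 2363 colonoscopies) are reproduced exactly in
the acceptance tests.

## The synthetic cohort generator

Individual-level screening data are rarely shareable, so
`generate_cohort()` provides a seeded stand-in calibrated to published
marginals of the KolosSal population (14,947 participants, ages 55–79):

* 49.0% male; per-sex age-band shares; per-sex prevalence of the most
  advanced finding (e.g. CRC 140/7323 in men, 73/7624 in women).
* Per-sex distal shares: the probability that *all* index-class lesions are
  distal is 118/140 (men) and 51/73 (women) for CRC, 646/971 and 345/544 for
  AA, under the descending-colon reach. This directly pins the no-referral
  sensitivities.
* Proximal-AN carriage arises mechanistically: an index AN placed not-all-
  distal, plus distal-CRC carriers receiving a synchronous proximal AA at
  12/118 (men) and 1/51 (women) — exactly the accounting that closes the
  published carrier totals (22 + 12 + 325 = 359 men; 22 + 1 + 199 = 222
  women). A single `prox_an_association` odds multiplier scales the
  synchronous-AA rate for sensitivity studies (default 1).
* The generator's AA prevalence uses the full published prevalence
  (985/7323 men), which includes two dozen cases whose location was missing
  in the source tables and which the published distal fractions exclude; the
  implied proximal-carrier rate therefore sits about one standard error above
  the printed ratio at n = 200,000 — inside the three-standard-error recovery
  band asserted in the acceptance tests.

Within-class shapes have no published counterpart and are invented,
documented synthetic choices: synchronous lesser-lesion multiplicities
(1–3 non-advanced adenomas, small Poisson extras), AA feature mixes (60%
large, otherwise villous/tubulovillous with occasional HGD), site weights
within the distal and proximal colon, and a rare (0.2% of hyperplastic
carriers) distal hyperplastic-polyposis pattern of ≥ 20 sigmoid polyps that
exercises the UK polyposis clause. Consequently the generator supports
*structural* and *calibration* testing — monotonicity along nested rules,
blinding, two-path consistency, recovery of the calibrated marginals — but
deliberately does **not** reproduce per-strategy referral counts of the
source population: those depend on the unpublished joint distribution of
distal findings, and are covered instead by the counts-only mode.

## Numerical and design choices

* Clopper–Pearson: `qbeta(alpha/2, x, n-x+1)` / `qbeta(1-alpha/2, x+1, n-x)`
  with the 0 and 1 boundary cases; zero denominators propagate `NA`.
* Rounding: half away from zero, applied only at render time.
* Participants with any unlocalised lesion are dropped entirely by default
  (`missing_location = "drop_participant"`), mirroring how unlocalised AA
  cases were removed from the source analyses; `"drop_lesion"` and `"keep"`
  are available.
* Problem sizes in the test suite were chosen for tight feedback: property
  tests use 100 cohorts of n = 2,000 and single cohorts of 2,000–60,000;
  parameter recovery uses one cohort of n = 200,000 (a few seconds), at which
  size the three-standard-error bands on the calibrated marginals are
  1–3 percentage points.

## Limitations

Bowel-preparation quality, endoscopist effects, FS-specific miss rates,
incomplete insertion, histopathology inter-laboratory variation and sessile
serrated lesions are not modelled. The generator's joint distribution of
distal findings and proximal AN is conditionally independent given sex and
most-advanced class (up to the association knob); real colons are likely
positively associated beyond this. Mixed multifocal CRC+adenoma carriers are
counted per endpoint class as described above; published tables do not state
their convention for these participants, which is why both detection modes
are implemented.
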