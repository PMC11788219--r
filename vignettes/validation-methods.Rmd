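---
title: "Validating administrative endometriosis diagnoses: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating administrative endometriosis diagnoses: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoval)
```

## The comparison being made

`endoval` treats surgically visualized disease, recorded on the rASRM
operative form, as the reference method, and ICD-coded administrative
claims as the test method. Both methods yield a per-participant binary
label for the overall diagnosis and for each of three non-exclusive
subtypes (SE, OE, DE); the package quantifies their concordance. Two
assumptions are load-bearing:

* **Participant-level comparison.** Claims are collapsed to one label set
  per participant; how many code rows support a label does not matter.
  This matches how validation of case-identifying algorithms is consumed
  (a participant is either captured or not).
* **The reference is treated as truth.** "Sensitivity" is the probability
  an administratively coded diagnosis exists given surgical confirmation,
  not a statement about the surgeon's accuracy.

## Reference method: typology rules

A confirmed case is classified from its lesion records:

* **DE** — any deep peritoneal or cul-de-sac lesion (deep operationalizes
  >5 mm invasion), or obliteration of the posterior cul-de-sac;
* **OE** — any deep ovarian lesion;
* **SE** — *only* superficial lesions: no OE/DE trigger present.

Three points were genuinely open and are package decisions:

* **SE is strict.** A case with superficial lesions *plus* a deep trigger
  reports `SE = FALSE`. The defining phrase "only superficial lesions"
  admits no other literal reading, though it makes SE mutually exclusive
  with OE/DE (see the generator section for the corollary).
* **Superficial cul-de-sac lesions count as superficial peritoneum**
  (SE-eligible); only deep ones trigger DE. The cul-de-sac is pelvic
  peritoneum, and the DE rule names depth, not mere location.
* **Cases without lesion information are assumed SE**, following the source
  cohort's handling of its 10 such cases. A degenerate record — confirmed,
  lesion info nominally available, but no lesions and no obliteration — is
  treated the same way, which keeps the classification total (every case
  receives a non-empty subtype set).

## Test method: code filter, subtype map, window

Any ICD-9 `617.x` / ICD-10 `N80.x` code is an endometriosis diagnosis.
Codes are compared case-insensitively with the dot optional (`N801` ≡
`N80.1`), because administrative extracts vary in dot usage.

The subtype map could not be copied from the original study (its mapping
table is supplementary material not available here), so the default is
reconstructed from the codes' anatomic-site titles: ovary (`617.1`/`N80.1`)
→ OE; pelvic peritoneum (`617.3`/`N80.3`) → SE; rectovaginal septum and
vagina, intestine (`617.4`, `617.5`/`N80.4`, `N80.5`) → DE; every other
endometriosis code (uterus, tube, scar, other, unspecified) counts toward
the overall diagnosis only (NOS). The map is a config entry (`map.<prefix>`
keys, longest-prefix matching), so a study with the true table can drop it
in; every shipped test that depends on the mapping states its map
explicitly.

The temporal rule removes claims dated more than `window_days` after the
participant's surgery, with `window_days = 30` as the operational meaning
of "one month" — calendar-month arithmetic is ambiguous at month ends, and
a fixed 30-day window keeps the boundary testable. The boundary is
inclusive (surgery + 30 is retained, + 31 removed). Claims *before* surgery
but inside the study period are retained: the enrolled population had no
prior endometriosis diagnosis by design, so pre-surgery endometriosis codes
are contemporaneous with the diagnostic work-up, not prior disease. Claims
outside the configured study period are removed regardless.

## Accuracy statistics

Seven measures per comparison: percent agreement, AUCR, sensitivity,
specificity, NPV, PPV, Cohen's kappa. Numerical choices:

* **AUCR is balanced accuracy.** With a single dichotomous test the ROC
  has one interior operating point, and the trapezoidal area under the
  two-segment curve is exactly (sensitivity + specificity)/2. No
  multi-threshold ROC is implemented.
* **Undefined metrics are `NA`, never 0.** A resample with no
  reference-positives has no sensitivity; imputing 0 would bias percentile
  CIs downward. Bootstrap replicates with undefined values are dropped and
  counted; if more than half are undefined the function stops and advises
  a larger sample. Kappa with both marginals constant is 1 under perfect
  agreement and undefined otherwise; an empty table is an error.
* **Percentile bootstrap, no bias correction.** Participants are the
  resampling unit (paired labels travel together, preserving the agreement
  structure kappa assumes), 1000 replicates by default, CI endpoints are
  the empirical α/2 and 1−α/2 quantiles (R's default type-7 quantile). BCa
  was deliberately not implemented: the method being emulated is the plain
  percentile method. A percentile CI need not bracket the point estimate
  in degenerate cases; the enforced invariant is `lower <= upper` within
  the metric's range.
* **Reproducibility.** All resampling is seeded from the config and runs
  under a save/restore of the caller's RNG state, so identical configs give
  bit-identical reports and library calls never perturb user code.
* Display formatting matches validation-study convention: two decimals for
  fractions, one decimal percent for agreement.

## Subgroup and error analyses

The subgroup report recomputes percent agreement, AUCR and kappa (with
bootstrap CIs) within race strata (Women of Color vs White) and ethnicity
strata (Hispanic vs non-Hispanic). Two compositions were not fully
specified in the source and are config switches with documented defaults:

* **Unknown race joins the Women of Color stratum by default**
  (`unknown_race_to_woc = TRUE`). The source study's stratum sizes are
  consistent with non-White plus unknown; with the switch on, the two race
  strata partition the cohort.
* **Missing ethnicity is excluded from the ethnicity contrast** (the
  source's stratum sizes sum to fewer than the cohort, implying exclusion).

Strata under 10 participants carry a small-sample warning rather than
being suppressed. False-negative error analysis bins each FN participant's
retained codes into an editable prefix vocabulary (laparoscopy/laparotomy,
pain, other symptom, other); false-positive analysis tallies which
administrative subtype flags (SE/OE/DE/NOS) the FPs carry. A participant
can count in several bins — the tallies profile participants, not codes.

## What the synthetic generator emulates

The generator's defaults state the emulated world and are not tuning
knobs: 412 participants, prevalence 0.42; subtype Bernoulli probabilities
among cases SE 0.827, OE 0.220, DE 0.335 (empty draws resampled); overall
coding sensitivity 0.88 and specificity 0.87, per-subtype values (SE
0.86/0.83, OE 0.82/0.92, DE 0.12/0.99) taken from the validation study's
*measured* table because no generative truth was ever published — a
modeling choice, not a claim; race white/WoC/unknown = 363/33/16 and
ethnicity 51/339/22 per the cohort's demographic table; rASRM stage drawn
from the published stage distribution; 10/173 of SE cases lack lesion
detail. Two rates are not stated anywhere and were chosen once as
field-realistic: `distractor_rate = 1.5` non-endometriosis codes per
participant (administrative records around a surgery are code-dense), and
`late_code_rate = 0.10` for an additional endometriosis code dated past
the window (follow-up coding exists but is the minority pattern).

Structural choices worth knowing:

* **The published subtype counts are jointly unattainable under strict
  SE.** SE 143 + OE 38 + DE 58 exceeds 173 cases, which requires SE to
  overlap OE/DE — impossible when SE means "only superficial". The
  generator samples the three subtypes independently at the stated
  probabilities and then drops SE whenever an OE/DE trigger was drawn, so
  every generated lesion list classifies back to its sampled subtype set.
  OE and DE marginals are preserved (inflated ~9% by empty-set
  resampling); the realized SE share among cases is ~0.43 rather than
  0.827. No setting of this generator can reproduce the published SE
  count and the strict rule simultaneously; the package privileges
  internal consistency.
* **Coding errors are participant-level.** One latent coded/not-coded draw
  per participant governs the within-window overall label exactly (the
  test label provably equals the latent draw), then 1–3 claim rows are
  emitted per concept. Measured overall sensitivity/specificity therefore
  recover the generating values up to binomial noise — the basis of the
  parameter-recovery test at n = 5000 (±0.02).
* **Subtype emission is conditional on being coded**: a true subtype's code
  appears with probability sens_s/sens_overall, a false subtype's with
  1 − spec_s, and a coded participant with no subtype code gets an
  unspecified (NOS) code. Consequently measured per-subtype *specificity*
  sits above the nominal input (a subtype false positive requires an
  overall code first), and NOS is the most common flag among false
  positives, with SE the most common *specific* subtype — matching the
  qualitative published error profile, not its exact counts.
* **Late codes are additional rows**, not replacements: the window filter
  has codes to remove without silently changing the effective sensitivity.
  An uncoded case that receives a late code is exactly a false negative
  created by the window rule.

What the generator does **not** emulate: insurance churn, longitudinal
care patterns, differential coding by demographic group (strata are
exchangeable by construction — the shipped subgroup checks test CI-width
ordering, not disparities), surgeon-level clustering, and any dependence
between subtype truth and coding quality beyond the per-subtype rates. A
green test on synthetic data therefore establishes that the pipeline
computes the intended quantities on data with the stated structure — not
that administrative data are valid in any new population.

## Degenerate inputs and edge behavior

Readers reject malformed dates (strict ISO 8601), unknown enum values,
duplicated participants and invariant violations with errors naming the
row; they never silently drop rows. Claims for participants absent from
the surgical table are readable but stop the pipeline with the offending
ids. An empty claims table is valid and yields sensitivity 0 / specificity
1. The window filter on an empty claim list returns an empty list; it is
idempotent by construction (retention is a pure predicate of each row).

## Known limitations

* The default code map is a documented reconstruction, not the original
  study's table; subtype-level results shift under a different map.
* Only structured diagnosis codes are considered — no clinical notes,
  pathology, or medication data, all of which could capture additional
  true cases.
* The bootstrap treats participants as exchangeable; there is no
  clustering by surgeon or facility.
* Published subtype-level and subgroup-level tables cannot be reconstructed
  exactly at desk scale (their 2×2 cells were never printed and are not
  integer-consistent with the rounded metrics); they are covered by
  property-style checks — parameter recovery, CI-width ordering — rather
  than value reproduction.
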