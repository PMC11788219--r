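# endoval

Validation of administrative-claims endometriosis diagnoses against a
surgical reference standard.

## The problem

Endometriosis research increasingly relies on administrative health data —
ICD diagnosis codes from inpatient, ambulatory-surgery and EHR billing
records — to assemble cohorts far larger than any single surgical study.
Before such cohorts can be trusted, the coded diagnoses need validating
against the clinical gold standard: disease visualized at laparoscopy or
laparotomy and recorded on the rASRM (revised American Society for
Reproductive Medicine) operative form. `endoval` is a reusable pipeline for
exactly that comparison, for the overall diagnosis and for three
non-exclusive subtypes:

* **SE** — superficial endometriosis: *only* superficial lesions on the
  ovary or peritoneum;
* **OE** — ovarian endometrioma: a deep ovarian lesion of any size;
* **DE** — deep infiltrating endometriosis: a deep (>5 mm invasion)
  peritoneal lesion or obliteration of the posterior cul-de-sac.

On the administrative side, endometriosis is any ICD-9 `617.x` / ICD-10
`N80.x` code; the code suffix (anatomic site) maps to a subtype through a
configurable prefix map, and codes dated more than a configurable window
(default 30 days) after the participant's surgery are removed.

Because the source data (a surgical research cohort linked to a statewide
population database) cannot be shared, the package ships a synthetic cohort
generator that reproduces the validation study's statistical structure —
412 participants, 42% surgical prevalence, imperfect participant-level
coding, distractor (pain/procedure) codes and out-of-window codes — so the
entire pipeline is testable end to end.

## The statistics

For paired reference labels (surgery) and test labels (claims) the pipeline
builds the 2×2 table (TP, FP, FN, TN) and reports, per comparison:

* sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
  PPV = TP/(TP+FP), NPV = TN/(TN+FN),
* percent agreement = (TP+TN)/N,
* AUCR = (sensitivity + specificity)/2 — for a single dichotomous test the
  empirical ROC curve has one operating point, so the trapezoidal area
  equals balanced accuracy,
* Cohen's kappa = (p_o − p_e)/(1 − p_e) with p_o the observed and p_e the
  chance agreement from the marginals.

95% confidence intervals come from a percentile bootstrap: participants are
resampled with replacement (paired labels travel together) 1000 times and
the empirical 2.5th/97.5th percentiles are taken. Error analysis profiles
the non-endometriosis codes of false negatives and the coded subtypes of
false positives; a subgroup analysis recomputes agreement, AUCR and kappa
within race and ethnicity strata.

## Worked example

```r
library(endoval)

spec <- generator_spec(rng_seed = 2024)   # 412 participants, 42% prevalence,
cfg  <- run_config(rng_seed = 2024)       # coding sens 0.88 / spec 0.87
coh  <- generate_cohort(spec, cfg)

ref <- reference_labels(coh$surgical)                  # surgical typology
tst <- test_labels(coh$claims, coh$surgical, cfg)      # ICD map + window
build_contingency(ref, tst, "overall")
#>           test
#> reference  positive negative
#>   positive      152       18
#>   negative       37      205

full_report(ref, tst, cfg)
#> Measure            overall           SE                OE                DE
#> percent_agreement  86.7%(83%, 90%)   91.7%(89%, 94%)   97.3%(96%, 99%)   86.7%(83%, 90%)
#> aucr               0.87(0.84, 0.90)  0.88(0.84, 0.93)  0.96(0.92, 0.99)  0.56(0.53, 0.61)
#> sensitivity        0.89(0.85, 0.94)  0.83(0.75, 0.91)  0.95(0.87, 1.00)  0.13(0.06, 0.21)
#> specificity        0.85(0.80, 0.89)  0.94(0.91, 0.97)  0.98(0.96, 0.99)  1.00(0.99, 1.00)
#> npv                0.92(0.88, 0.95)  0.96(0.93, 0.98)  0.99(0.99, 1.00)  0.87(0.83, 0.90)
#> ppv                0.80(0.75, 0.86)  0.77(0.68, 0.86)  0.80(0.67, 0.91)  0.89(0.64, 1.00)
#> kappa              0.73(0.66, 0.80)  0.75(0.66, 0.83)  0.85(0.75, 0.93)  0.19(0.08, 0.32)
```

Reading the output: of 170 surgically confirmed cases, 152 also carry a
within-window endometriosis code (sensitivity 0.89); kappa 0.73 is
substantial chance-corrected agreement. The deep-infiltrating subtype shows
the signature pattern of administrative data — near-perfect specificity
(a coded DE is almost always real) but very low sensitivity (most surgical
DE is never coded), so its kappa is slight even though raw agreement is
87%.

The same cohort's error profiles:

```r
retained <- filter_claims_window(coh$claims, coh$surgical, cfg)
fn_ids <- ref$participant_id[ref$overall & !tst$overall]
error_analysis_fn(fn_ids, retained, cfg$fn_vocab)
#> laparoscopy_laparotomy                   pain          other_symptom
#>                      8                      5                      8
#>                  other
#>                      2
```

i.e. most false negatives still have surgery or symptom codes at the time
their endometriosis code is missing.

A one-call driver reads CSVs and writes every report
(`accuracy_table.csv/.txt`, `subgroup_table.csv`, `error_fn.csv`,
`error_fp.csv`, `run_log.txt`):

```r
run_pipeline("surgical.csv", "claims.csv", cfg, out_dir = "out")
```

and a CLI wraps both stages (`inst/cli/validate.R`, installed under
`system.file("cli", "validate.R", package = "endoval")`):

```sh
Rscript validate.R synth --n 412 --seed 1 --out data/
Rscript validate.R run --surgical data/surgical.csv --claims data/claims.csv --out reports/
```

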