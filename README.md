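# fibrodetect

Scoring and validation analytics for the FibroDetect fibromyalgia
screening questionnaire, with a calibrated synthetic-cohort generator.

Fibromyalgia is chronically under- and mis-diagnosed in primary care:
symptoms are heterogeneous, overlap with other pain conditions, and the
ACR classification criteria (widespread pain plus a tender-point
examination) are rarely applied correctly outside specialist settings.
FibroDetect is a 14-question self-administered screening leaflet whose
final scoring model keeps six physical-burden questions plus a
self-recognition question, coded into nine binary items:

| item | rule |
|---|---|
| `B_UPPER` | ≥ 1 upper-body silhouette area ticked (head, neck, shoulders) |
| `B_ARM` | ≥ 1 upper-limb area ticked |
| `B_LEG` | ≥ 1 lower-limb area ticked |
| `PAIN_FREQ` | pain every day or almost every day |
| `PAIN_KINDS3` | ≥ 3 of 8 kinds of pain ticked |
| `TIRED_FREQ` | tired every day |
| `EFFORT` | much more tired after physical effort |
| `SYMPT7` | ≥ 7 of 17 symptoms ticked |
| `RECOG` | "absolutely" recognises themselves in the questions |

The score is the plain sum `S = Σ items ∈ {0, …, 9}`, computed only when
all nine items are answered, and partitioned into decision bands
`S ≤ 3` (unlikely), `4–5` (indeterminate) and `S ≥ 6` (refer). The
package implements, as composable tibble-in/tibble-out functions:

* **scoring** — exact item coding, the completeness rule, bands
  (`code_items()`, `compute_score()`, `classify_band()`,
  `score_responses()`);
* **item-reduction machinery** — per-item missing percentages, odds
  ratios with Woolf 95% intervals and Haldane zero-cell correction,
  PLS-DA (NIPALS, pairwise-available handling of missing entries) with
  variable importance in projection, and the iterative multi-criteria
  reduction loop with a replayable decision trace
  (`item_diagnostics()`, `plsda_fit()`, `reduce_items()`);
* **ROC analysis** — integer-threshold ROC curves whose trapezoidal AUC
  equals the Mann–Whitney concordance bit for bit, operating points, and
  threshold selection under the sensitivity ≥ 95% / specificity ≥ 50%
  rule (`roc_curve()`, `select_threshold()`, `evaluate_scores()`);
* **synthetic cohorts** — a single-latent-trait probit generator for
  labelled questionnaire cohorts with MCAR missingness, plus
  simulation-based calibration to published score summaries
  (`group_config()`, `generate_cohort()`, `calibrate_generator()`), with
  pre-calibrated configurations for the four validation-study-style
  groups (`shipped_group_config()`).

Fitted objects have broom-style `tidy()`/`glance()` methods and
`autoplot()` plots; a thin command-line wrapper over the same functions
ships at `inst/cli/fibrodetect.R`.

## Worked example

Simulate the two pre-calibrated control-style groups (158 fibromyalgia,
154 non-fibromyalgia respondents), score them, and evaluate the
contrast:

```r
library(fibrodetect)

cohort <- dplyr::bind_rows(
  generate_cohort(shipped_group_config("fm")),
  generate_cohort(shipped_group_config("non_fm")))
validate_cohort(cohort, "FM", "NON_FM")
#> Evaluation: FM vs NON_FM, AUC = 0.854
#> Selected threshold 5 (sens 97.4%, spec 43.7%; rule infeasible)
#>
#> Band table:
#>    group n_total   n n_missing mean   sd median q1 q3 min max n_low n_mid
#> 1     FM     158 156         2 7.58 1.40      8  7  9   0   9     2     8
#> 2 NON_FM     154 151         3 4.85 2.12      5  3  6   0   9    45    49
#>   n_high pct_low pct_mid pct_high
#> 1    146    1.28    5.13     93.6
#> 2     57   29.80   32.45     37.7
#>
#> Threshold table:
#>    threshold sensitivity specificity
#> 1          0       1.000      0.0000
#> ...
#> 7          6       0.936      0.6225
#> 8          7       0.827      0.7682
#> ...
```

Reading the output: the synthetic fibromyalgia group concentrates in the
referral band (score ≥ 6) and the non-fibromyalgia group spreads across
all three bands, giving an AUC of about 0.85 — a random fibromyalgia
respondent outscores a random non-fibromyalgia respondent about 85% of
the time. At the conventional referral cut-off of 6 the operating point
is sensitivity 93.6% / specificity 62.3%. No integer threshold reaches
95% sensitivity with at least 50% specificity on this draw, so the
selector flags the strict rule infeasible and returns the
best-specificity point that still meets the sensitivity target; the full
threshold table is always printed so any operating point can be read
off directly.

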