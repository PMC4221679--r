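---
title: "Methods: scoring, discriminant modelling and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, discriminant modelling and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrodetect)
```

This vignette is the package's own account of the statistical machinery
it implements: the questionnaire score, the item-reduction procedure,
the ROC analysis, and the synthetic-cohort generator, together with the
design decisions taken where the design was genuinely open.

## The screening score

The instrument asks fourteen questions; the scoring model uses seven of
them, coded into nine binary items (three silhouette-region indicators
plus six single-question indicators, listed in `item_names()`). Each
item is 1 when its endorsement rule fires, 0 when the question was
answered without firing it, and missing when the question was left
unanswered. Two coding conventions deserve emphasis:

* **Answered-empty checklists code 0, not missing.** A respondent who
  reaches a checklist and ticks nothing has answered "none apply"; only
  a question left entirely blank is missing. The CSV dialect therefore
  distinguishes an empty cell (missing) from the sentinel `NONE`
  (answered-empty). Observed per-item missing rates in completed
  screening leaflets run from roughly zero to the mid-teens of percent,
  which is only consistent with blank checklists being treated as
  answers.
* **The score exists only for complete item vectors.** `S` is the plain
  sum of the nine items, so `S` ∈ 0..9; any missing item sets `S`
  missing, with no imputation or partial credit. Band percentages
  (`≤ 3`, `4–5`, `≥ 6`) are always computed over non-missing scores, and
  `classify_band()` refuses missing input rather than defaulting.

The 16-area silhouette taxonomy is a package convention (the published
coding consumes only region-group membership); it ships as a versioned
YAML file with explicit region tags. Trunk areas are tagged
`TRUNK_OTHER` and feed no coded item: the coding rules name only
head/neck/shoulders, arms and legs, so counting trunk ticks toward the
upper body would silently change item semantics.

## Item diagnostics and PLS-DA

Item reduction uses four criteria, evaluated in a fixed order: per-item
missing percentage, the odds ratio's 95% confidence interval, VIP from a
PLS-DA fit, and clinical relevance. The odds ratio is the cross-product
ratio of the item × group 2×2 table with the Woolf log-interval
`exp(log OR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`; zero cells get the
Haldane–Anscombe +0.5 correction so rare items keep finite estimates.

`plsda_fit()` is a NIPALS PLS1 on the centred, unit-variance-scaled item
matrix against the centred 0/1 group indicator — unit-variance scaling
is the convention of the multivariate software culture this analysis
style comes from, and it is recorded in the fitted object so
alternatives reproduce. Missing entries are handled by
pairwise-available accumulation: every inner regression (weights,
scores, loadings) sums over observed entries only, so incomplete
respondents still inform the fit. Variable importance is

$$\mathrm{VIP}_j = \sqrt{\,p \sum_a SS_a\, w_{ja}^2 \Big/ \sum_a SS_a\,},$$

with `SS_a` the label sum of squares explained by component `a`; squared
VIPs sum to `p` by construction, and `VIP > 1` is the conventional
importance cut. Two identities anchor the implementation and are tested
numerically: ΣVIP² = p on every fit (tolerance 1e-8), and equality of
full-component PLS fitted values with ordinary least squares on
complete full-rank data (tolerance 1e-6). The default of two components
is a convention — parsimonious for nine binary items — exposed as an
argument; no cross-validation of the component count is implemented
because none is defined for this procedure.

`reduce_items()` drops one item per pass: the first violated criterion
in the order missing → OR → VIP nominates its failures, and the
lowest-VIP failure is dropped (ties broken toward higher missing
percentage, then lexicographic id — determinism is a requirement, and
VIPs change after each refit, which is why drops are one at a time).
Clinical flags are inputs, never inferred: expert judgment is not
reproducible computation, so a flagged item is retained and the
override recorded in the trace. The trace is a complete, replayable log
of every decision with the values that fired it. The missing-percentage
cap defaults to 15% — just above the top of the observed missing-rate
range, consistent with no item having been dropped for missingness
alone — and is configurable.

## ROC analysis and the threshold rule

Scores are integers, so candidate thresholds are the integers 0–10
(support plus one); classification is positive when `score ≥ t`, which
makes the referral band `≥ 6` coincide with threshold 6. The trapezoidal
AUC is computed with an integer-count numerator and a single division,
which makes it *bit-for-bit* equal to the tie-corrected Mann–Whitney
concordance probability — the acceptance suite checks exact equality on
1,000 random cohorts rather than equality within tolerance.

`select_threshold()` implements the stated selection rule: among
thresholds with sensitivity ≥ 95% and specificity ≥ 50%, take the
highest-specificity one (ties toward the higher threshold). On real
operating tables this rule can be infeasible — the published operating
point at the referral cut-off (sensitivity 77%, specificity 61% on the
development contrast) is not the point the 95%/50% rule would select,
and the source analysis does not explain the reconciliation. The
package therefore refuses to guess: infeasibility is a *flagged result*
carrying the best-specificity point that still meets the sensitivity
target, and every report prints the full integer-threshold table so
both readings stay visible.

## The synthetic-cohort generator

No respondent-level data are published, so the package generates its
own. The generative model is deliberately the simplest structure that
produces correlated, right-shifted item profiles:

* one latent severity trait `z ~ N(mu, 1)` per respondent;
* per-answer latents `l = √rho·z + √(1−rho)·e`, so `rho` is the share
  of item variance carried by the common trait and `mu` the group
  separation;
* probit thresholds for ordinal answers (the level that codes 1 sits
  above the item's offset; adjacent levels are `ordinal_gap` apart);
* binomial checklist counts with latent-linked success probability
  `Φ(l − offset)` (8 kinds of pain, 17 symptoms), tokens then drawn
  uniformly without replacement;
* silhouette regions ticking when their region latent clears its
  offset, with `1 + Binomial(3, 0.3)` areas inside an active region and
  a low-rate latent-linked trunk background;
* MCAR missingness per question, bounded at 15% per question.

Defaults encode the study-style conditions: the four shipped group
configurations carry the validation-study group sizes (137/139/158/154)
and were calibrated once to the published per-group summaries (mean
scores 6.8/5.1/7.6/4.7 and band proportions), with per-question missing
rates set so the missing-score fraction matches each group's published
scored-respondent count. Richer structures (multiple factors,
informative missingness, demographic covariates) are intentionally out
of scope — no mechanism for them is published.

Randomness is consumed as a fixed-width block of 65 uniforms per
respondent from one master-seeded stream, then transformed
deterministically (`qnorm`, `qbinom`, ranking for without-replacement
draws). This gives byte-identical regeneration and a substream
property: appending respondents never perturbs earlier ones.

### Calibration

`calibrate_generator()` matches moments by damped iteration because band
proportions have no closed form under this model: simulate `max_n`
respondents with common random numbers, update `mu` from the mean-score
error (or, with band-only targets, from the high-minus-low band error)
and `rho` from the SD error, damping 0.5, iteration cap 50. The update
slopes are order-of-magnitude estimates (about 1.5 score points per
latent unit; about 3 SD points per unit of `rho`) — damped fixed-point
iteration only needs the scale to be roughly right. Convergence is
declared when every targeted band proportion is within the tolerance
(default 0.02; the shipped calibrations used 0.01 so that an
independent regeneration stays comfortably inside 0.02) and infeasible
targets (band proportions summing past 1, means outside 0–9) are
rejected before any simulation. Two location/dispersion parameters
cannot reproduce five summaries exactly for every group: the
fibromyalgia profile converges fully, while the flatter three-band
profiles of the other groups match their means and SDs exactly and
their bands to within about five percentage points — the returned
object reports achieved summaries and a per-iteration history either
way.

### Problem sizes used by the test suite

Unit tests run at cohort sizes of tens to a few hundred; distributional
properties (monotonicity in `mu`, null correlations at `rho = 0`,
missing-score fractions) use 4,000–10,000 respondents with fixed seeds
and 3·SE (or family-wise-adjusted) bounds; the calibration check runs
at 20,000, the size at which Monte-Carlo noise (SE ≈ 0.003 on a band
proportion) is negligible against the 0.02 acceptance width. The full
suite completes in well under a minute on a single core.

## What passing tests do and do not show

The generator emulates marginal score distributions, inter-item
correlation through one factor, and MCAR missingness. It does not
emulate real response styles (straight-lining, item-order effects),
informative missingness, demographic structure, or the content of the
unscored questions (kept as opaque blocks). Tests passing on synthetic
cohorts therefore validate the *machinery* — coding, scoring,
diagnostics, model search, ROC arithmetic, calibration — not the
clinical performance of the instrument on any real population; the
published cohort-level AUCs depend on unpublished patient-level data
and are not reproducible from summaries.

## Known limitations

* The 16-area taxonomy and its region tags are a convention; any
  16-code taxonomy with correct region groups preserves the coding
  semantics, but area-level outputs are not comparable across
  taxonomies.
* Respondents with missing scores receive no fallback guidance (none is
  defined); downstream percentage arithmetic excludes them.
* PLS-DA missing-data handling follows the pairwise-available NIPALS
  convention; other conventions (EM imputation, complete-case) would
  give slightly different VIPs on incomplete data.
* `select_threshold()` applies the stated rule verbatim; users wanting
  the published referral cut-off should read it off the threshold table
  rather than expect the rule to select it.
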