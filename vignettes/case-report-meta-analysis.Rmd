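---
title: "Aggregating narrative case reports: the evidence-classification model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregating narrative case reports: the evidence-classification model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacase)
```

## The problem

In rare diseases most published evidence about a treatment is narrative
case reports. Classical meta-analysis needs comparable effect sizes and
cannot use them; qualitative review discards the counting information they
do carry. `metacase` implements a quantitative alternative: fix a list of
outcomes in advance, score each outcome in each case report as *modified*
or *not modified* after treatment, and treat the per-outcome count of
positive cases among all analyzed cases as the aggregate evidence signal.
The motivating application is enzyme replacement therapy with idursulfase
in mucopolysaccharidosis type II (Hunter syndrome), scored against the
strength-of-evidence (SOE) grades of an independent clinical-study
meta-analysis.

## Scoring model

Every case contributes a denominator count to every outcome: an outcome a
report does not mention is scored *not modified*. This is deliberately
conservative — case reports preferentially describe what improved, so
treating silence as absence biases the positive proportions downward, not
upward.

Two confirmatory rules are implemented:

* **strong** — a benefit outcome is positive only when improvement is
  mentioned *and* the report either describes the evaluation method or
  gives a quantitative measure;
* **weak** — mention of improvement suffices.

Safety outcomes are scored on impairment rather than improvement.
Infusion-related reactions count (under both rules) only when the reaction
forced a change in the treatment dose, via the dedicated
`irr_dose_change` flag; mild reactions managed without dose modification
carry no signal about harm at the aggregate level. Antibody development,
the other safety outcome, follows the benefit-shaped rule (documented
detection under strong scoring, mention under weak), which is why its
strong and weak counts coincide on the packaged corpus. By construction
strong positivity implies weak positivity, so for every outcome
`k_strong <= k_weak`.

## Futility test and evidence groups

For each outcome with count *k* among *n* cases we test
H0: true modification proportion ≤ `p0` with the exact one-sided binomial
tail P(X ≥ k), X ~ Binomial(n, `p0`). The default boundary `p0 = 0.05` is
the conventional null response rate of single-arm futility designs: a
treatment under which at most 5% of published cases show modification is
considered inactive for that outcome. The test is a screening device — the
method cannot estimate effect sizes, only whether the proportion of
positive reports is incompatible with futility.

Multiplicity across the `nr` outcomes is handled with
Benjamini–Hochberg critical values `r/nr × q` at FDR level `q = 0.10`.
Two grouping rules are available:

* `per_rank` (default): an outcome is *acceptable evidence* iff its own
  p-value is at or below its own critical value;
* `step_up`: the orthodox BH step-up, which additionally accepts any
  outcome ranked below an accepted one.

Ranks are *dense* with tie groups sharing their minimum rank: sorted
p-values 0.001, 0.177, 0.177, 1 get ranks 1, 2, 2, 3. Sharing the lowest
rank is conservative (the critical value grows with rank), and dense
numbering reproduces the published rank columns. Ties are detected by
exact equality of full-precision p-values, which is safe because ties can
only arise from identical counts. The two rules coincide whenever the
sub-threshold p-values form a prefix of the ranking — they do on the
packaged corpus, and the test suite asserts it — but can diverge
elsewhere, which is why both are exposed.

For display, p-values are rounded to three decimals and values below
1e-4 print as `< 0.0001`; proportions print as whole percents rounded
half away from zero (10/11 → 91%), matching the conventions of the
published tables.

## Concordance with the gold standard

The classification is validated against the SOE grades
(insufficient/low/moderate/high, ordinal scores 1–4) that the
clinical-study meta-analysis assigned to the same outcomes. Two views:

* **2×2 validity** — test-positive = acceptable evidence group,
  gold-positive = moderate-to-high SOE; sensitivity, specificity,
  predictive values and accuracy each carry an exact Clopper–Pearson
  interval (beta-quantile closed form). Indices with empty denominators
  are reported as undefined rather than invented.
* **Relative agreement** — tie-corrected Spearman correlation between
  per-outcome positive counts and SOE scores: midranks, then the
  product-moment correlation. With the heavy ties of count data this is
  the correct estimator; the no-tie shortcut formula
  `1 − 6Σd²/(n(n²−1))` gives 0.83 on the primary strong counts where the
  midrank estimator gives the published 0.82. The confidence interval
  uses the Fisher z transform with standard error `1/√(n−3)` and normal
  quantiles, undefined when |rho| = 1 or n ≤ 3.

## The packaged corpus is a reconstruction

The individual per-case outcome flags behind the published MPS-II
analysis were never printed; only marginal counts were. The shipped
fixture (`mpsii_corpus()`) is therefore a *synthetic reconstruction*:
56 cases whose flags were chosen once so that every printed marginal is
reproduced simultaneously — 44 cases from 25 publications in the primary
set, 36 from 21 excluding congress communications, 33 from 22 excluding
clinical-meta-analysis overlap, and the per-outcome strong and weak
counts of the primary set. Which particular case carries which positive
is arbitrary and frozen in the CSV. Per-outcome counts in the three
sensitivity sets were likewise not printed; the reconstruction fixes
them to values consistent with the published confusion tables and
whole-percent agreement statistics of the sensitivity analysis.

One published figure cannot be honored: 38 total publications is
incompatible with 25 primary publications when only 12 cases postdate
the cutoff (13 extra publications would need at least 13 extra cases).
The reconstruction has 37 publications and treats the case counts as
authoritative. Two further published numbers are internal
inconsistencies that the package intentionally does not reproduce: the
weak-method table prints p = 0.014 for a count of 8/44 although the
exact value is 0.001 (the strong-method table prints 0.001 for the same
count), and its critical values at ranks 7 and 8 appear transposed
relative to `r/nr × q`.

## Synthetic corpora and operating characteristics

`simulation_scenario()` + `generate_corpus()` emulate the statistical
structure the analysis assumes: per-outcome true modification
probabilities; a reporting-quality model (a true modification is always
mentioned and is documented at strong level with probability
`prob_strong_documentation`, default 0.7; an unmodified outcome is
reported negatively with probability 0.3); and an explicit
publication-bias mechanism — a case whose report mentions no
modification at all is dropped with probability `publication_bias`.
Dropping only fully-negative cases inflates observed positive
proportions above the truth, which is the bias direction one expects of
published case series; the defaults keep the mechanism off because its
magnitude is a conjecture, not a measured quantity.

Outcomes are drawn independently within a case by default (the analysis
assumes no dependence structure); `severity_sd` optionally adds a shared
logit-normal per-case severity factor for users who want correlated
outcomes. Generated corpora do not emulate other features of real case
reports — covariates, dosing, follow-up time, free text — so passing
operating-characteristic checks demonstrates control of the statistical
procedure under the stated model, not robustness to everything real
corpora do.

`operating_characteristics()` replays the full
generate → count → test → classify pipeline; replicate *r* uses seed
`seed + r − 1`, so any replicate is reproducible independently of how
many are run. The packaged checks use corpora of 44 cases and 11
outcomes with 2000 replicates under the all-null scenario (every true
probability equal to `p0`), verifying that per-outcome acceptance rates
stay below `q` plus Monte-Carlo error, and 400 replicates for the power
check at a true probability of 0.45, the magnitude observed for the
urinary-GAG outcome.

## Numerical and design choices

* The binomial tail uses the exact incomplete-beta form
  (`pbinom(k−1, n, p0, lower.tail = FALSE)`); the test suite verifies
  agreement with direct log-space summation to 1e-12 over the full grid
  k ≤ n ≤ 60.
* `per_rank` is the default grouping rule because it is the rule the
  published tables apply, even though the procedure is conventionally
  described as step-up; the orthodox rule is one flag away.
* Degenerate inputs return signals, not crashes: zero-trial intervals
  and zero-variance correlations are `NA`, an empty analysis set flows
  through counting (k = n = 0, p = 1) to an unacceptable classification.
* Filtering to an analysis set is conjunctive, idempotent, and records
  the resulting case and publication counts in the dataset provenance.
* Cases published only in aggregated form are representable
  (`aggregated_form = TRUE`) but excluded from every shipped analysis
  set, since aggregated series are not narrative case reports.

## Limitations

The method classifies evidence; it cannot estimate effect sizes, and a
corpus of case reports cannot replace controlled trials. The
reconstruction ties validation to published marginals, not to source
data. The futility boundary is a design parameter: boundaries below 5%
admit weakly supported outcomes (specificity and positive predictive
value fall), boundaries above 5% miss genuine signals (sensitivity and
negative predictive value fall) — the boundary sweep in the test suite
demonstrates both directions on the packaged corpus.
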