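---
title: "Mining significant risk combinations and stratifying heart-failure risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining significant risk combinations and stratifying heart-failure risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamprisk)
```

## The problem

New-onset heart failure (HF) in the general population is driven by the
joint presence of many ordinary clinical factors — blood pressure, age,
glycemia, lipids, habits, prescriptions — none of which predicts it well
alone. The design this package implements is a two-cohort ("two-protocol")
screen over annual health check-up data:

1. **Protocol 1 (analysis cohort).** Binarize the clinical variables into
   indicator items and mine *every* combination of up to four items that is
   significantly associated with four-year HF onset, with family-wise error
   control over the combinatorial family.
2. **Protocol 2 (validation cohort).** For each person in an independent
   cohort, count how many mined combinations they carry, bin the counts
   into ordered groups, and ask whether HF incidence rises with the number
   of matched combinations (incidence table, trend test, Kaplan–Meier).

The real data behind this design — JMDC insurance-claims check-ups for
308,205 people followed 2010–2014, with a 32,547-person analysis cohort
experiencing 325 events — is proprietary. The package therefore ships a
seedable synthetic-cohort simulator with the same statistical skeleton, so
the entire pipeline is exercisable and testable end to end.

## The multiple-testing engine (LAMP)

With $M$ items there are on the order of $2^M$ candidate combinations.
Plain Bonferroni over all of them destroys power. The limitless-arity
multiple-testing procedure (LAMP) exploits Tarone's observation that a
discrete test cannot produce arbitrarily small p-values: a combination
carried by $\sigma$ of $N$ persons, of whom $n_p$ are positives, has
one-sided Fisher p-value at least

$$f(\sigma) = \binom{n_p}{\sigma} \Big/ \binom{N}{\sigma},$$

the probability that all $\sigma$ carriers are positives. $f$ is strictly
decreasing in $\sigma$ (up to $n_p$), so rare combinations are *untestable*:
they can never reach a small enough p-value to matter, and they need not be
counted in the correction.

Let $k_D(\sigma)$ be the number of combinations (arity $\le 4$) carried by
at least $\sigma$ persons — computable only by mining, and non-increasing
in $\sigma$. `calibrate_sigma_star()` selects

$$\sigma^* = \max\{\sigma : f(\sigma) \ge \alpha / k_D(\sigma)\},$$

scanning upward from the support floor: below the crossing point the
corrected level $\alpha/k_D(\sigma)$ is still so small that sub-threshold
combinations are provably hopeless, so the family can be pruned to the
$k_D(\sigma^*)$ frequent ones without missing any significant hypothesis.
Testing those at level $\alpha / k_D(\sigma^*)$ (and reporting Bonferroni
products $\min(1, p \cdot k_D(\sigma^*))$ as adjusted p-values) keeps the
family-wise error rate below $\alpha$.

Two practical points about this selection rule:

* **Rare outcomes fall back to the floor.** With a ~1% outcome, $f(10)$ is
  already astronomically small, the balance condition fails at the first
  scanned value, and $\sigma^*$ equals the pre-declared support floor of 10
  persons. The tested family is then exactly "arity $\le 4$, support
  $\ge 10$", Bonferroni-corrected by $k_D(10)$ — which is precisely how a
  large sparse cohort behaves, and remains FWER-valid because the floor is
  declared before seeing the data. The floor of 10 reflects the practical
  requirement that a reportable rule hold for at least 10 people.
* **Direction in $\alpha$.** Raising $\alpha$ raises the corrected level,
  so the balance fails earlier and $\sigma^*$ (weakly) *decreases* — more
  hypotheses become testable at a laxer level. This is the Tarone
  direction, and the property suite asserts it.

The comparison bound is $f(\sigma)$ by default. The tight form of the
exclusion argument uses $f(\sigma - 1)$ (a combination with support below
$\sigma$ has minimum p-value at least $f(\sigma-1)$); that variant is
available as `bound = "f_sigma_minus_one"` and yields a slightly larger
$\sigma^*$. The default is the conservative reading.

### Sidedness

The Fisher test is one-sided (enrichment of carriers among positives),
because $f(\sigma)$ *is* the one-sided minimum: the bound and the test must
use the same tail or the testability argument breaks. The methodology this
design descends from describes the corrected family once as "t-tests" and
elsewhere as Fisher's exact tests; the $f(\sigma)$ bound only makes sense
for the exact test, so Fisher is used throughout.

### Minimality filtering

If $\{A\}$ is significant, $\{A, B\}$ being significant is usually a
corollary. `minimal_filter()` removes every significant combination whose
condition strictly contains another retained significant condition,
proceeding by ascending arity; the result is an antichain under inclusion.

### Implementation notes

* Enumeration is a depth-first search over items in lexicographic name
  order with anti-monotone pruning (an infrequent prefix is never
  extended); emission order, and hence all downstream output order, is
  deterministic.
* $f(\sigma)$ is evaluated as `exp(lchoose(n_p, s) - lchoose(N, s))`; the
  hypergeometric tail uses `stats::phyper`. Both are exact to double
  precision at cohort scale; tests cross-check against explicit
  tail summation and `stats::fisher.test`.
* Significance is the strict inequality `raw_p < alpha / k_D(sigma*)`,
  matching the exclusion argument; ties at the boundary (possible in a
  discrete test) are therefore not rejected.
* `k_D(sigma)` for the calibration scan is obtained by enumerating once at
  the support floor and tail-counting the support distribution, which is
  exact for every $\sigma \ge$ floor.

## Stratification (Protocol 2)

`match_count()` counts, per validation person, the rules whose condition
they fully carry; `assign_group()` bins counts into the six inclusive
ranges 0, 1–50, 51–100, 101–150, 151–200, 201–250. Counts above the top
range are placed in an explicit overflow bin with a warning by default
(clamping and erroring are available); the published design never needed
one, but the simulator can produce arbitrary rule sets.

The trend across ordered groups is tested with the **Cochran–Armitage**
statistic on integer scores $0..G-1$ (signed $Z$, two-sided p), with a
chi-square homogeneity test reported alongside. The source methodology
names "Cochran's Q" here; Cochran's Q applies to matched repeated binary
measurements, not independent ordered groups, so Cochran–Armitage — which
tests exactly the stated hypothesis, that incidence increases with the
group index — is the primary method and the naming discrepancy is simply
documented. Mid-range count scores can be supplied via the `scores`
argument.

Kaplan–Meier curves use the discrete product-limit estimator on the annual
grid: events happen at integer years, event-free persons are
administratively censored at the end of follow-up (no death information is
modelled — the emulated data set had none). With censoring only at year
$T$, $S(T) = 1 - (\text{group incidence})$ exactly; the tests assert this
identity, and cross-check the estimator against `survival::survfit`.

## The synthetic-cohort simulator

`simulation_config()` + `generate_raw_cohort()` emulate the check-up data
the design was built for:

* **Variables.** 14 continuous labs/vitals parameterised by the published
  whole-cohort medians and interquartile ranges (normal fits for
  symmetric variables, log-normal for right-skewed ones such as
  triglycerides and gamma-GTP), six binary habit/prescription indicators
  and five categorical findings with plausible population rates. Drawn
  values are rounded to reporting precision.
* **Binarization.** The default scheme maps these to 36 indicator items at
  standard clinical guideline cutoffs (140/90 and 130/85 blood pressure,
  BMI 25, waist 85 cm, HbA1c 5.6/6.0/6.5, LDL 140/160, HDL 40, TG 150,
  AST/ALT 31, gamma-GTP 51, urate 7, Hb 12), including negation items
  (non-smoker, no exercise) because protective combinations are part of
  the search space. The cutoffs live in an editable scheme object;
  quantile-based schemes can be built with the same constructors.
* **Onset model.** Each person's annual hazard is the baseline
  (default 0.0025/year) times the product of the multipliers of every
  planted rule they match, capped at 1 (cap events are counted and
  reported). Onset is the first success among independent annual
  Bernoulli trials over 4 years. This is the simplest mechanism consistent
  with data recorded as presence/absence of diagnosis per check-up year;
  multiplicative composition is the conventional choice for rates.
* **Calibration.** The defaults (three planted rules of hazard ratio 2–3
  jointly covering ~4% of persons) give an expected four-year event count
  of about 345 in a 32,547-person cohort, within the binomial 3-SE band of
  the 325-event benchmark; the acceptance suite verifies this over 10
  seeds.
* **Determinism.** All randomness flows from the config seed (the onset
  stage draws its own sub-seed from the same stream), so identical
  configurations are bit-reproducible, and a rule with multiplier 1 leaves
  the cohort unchanged draw for draw — which also makes paired
  monotonicity experiments exact rather than statistical.

What the simulator does **not** emulate: correlations among labs (age does
not shift blood pressure; items are conditionally independent given the
planted rules), ICD-coded claim structure or free-text prescriptions,
secular trends across check-up years, informative censoring by death, and
missingness (an optional MCAR rate exists for robustness tests, with
missing values binarized as item absence and the imputed count logged).
Passing tests on synthetic cohorts therefore demonstrate the *procedure's*
correctness and error control, not that real check-up data satisfies the
simulator's independence assumptions.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha` | 0.05 | FWER | conventional familywise level |
| `max_arity` | 4 | items | combinations larger than 4 cannot reach 10 carriers at this scale, and the search cost grows combinatorially |
| `support_floor` | 10 | persons | pre-declared practical relevance threshold; lower bound of the $\sigma^*$ scan |
| `baseline_annual_hazard` | 0.0025 | /year | reproduces ~1% four-year incidence (~2.5/1000 person-years) |
| `follow_up_years` | 4 | years | annual check-ups 2010–2014 |
| `split_fraction` | 32547/308205 | — | the published analysis/validation allocation ratio |
| binning | 0, 1–50, …, 201–250 | rules | the published six-group scheme |

## Problem sizes used by the test and acceptance suites

The suites were designed around desk-scale instances: exhaustive-oracle
equivalence on 50 random instances with $N \le 200$, $M \le 12$; FWER on
500 label permutations of a 500×15 matrix; planted-rule recovery over 20
replicates at $n = 5000$ with hazard ratio 5; simulator calibration at the
full $n = 32{,}547$ over 10 seeds. The analysis scripts under `analysis/`
run the full 308,205-person design (mining takes well under a minute).

## Known limitations

* The calibration fallback means that for rare outcomes the procedure is
  plain Bonferroni over the pre-declared frequent family — correct but
  conservative; the discrete tests make realized FWER far below $\alpha$.
* With conditionally independent items, a planted rule's correlated
  shadows (e.g. the 130-mmHg item when the rule uses the 140-mmHg item)
  can also reach significance; the minimality filter removes supersets but
  not correlated siblings, exactly as in real data.
* The simulator's independence structure means the six published strata
  are not reproduced in shape: with a handful of planted rules, match
  counts concentrate near zero. The published group counts are shipped as
  reference constants (`jmdc_reference()`) for the arithmetic checks
  instead.
* Person-year arithmetic uses cohort-size × follow-up (no subtraction of
  post-onset years), matching how the ~2.5/1000 benchmark is quoted.
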