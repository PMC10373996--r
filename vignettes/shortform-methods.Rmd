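---
title: "Deriving short-form health literacy tests: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving short-form health literacy tests: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shortform)
```

## The problem

The TOFHLA (Test of Functional Health Literacy in Adults) and its Danish
adaptation measure functional health literacy with 67 items — 17 numeracy
items that require a trained interviewer and 50 reading-comprehension items
in a cloze format — scored on a 0–100 scale and classified as inadequate
(0–59), marginal (60–74) or adequate (75–100). At about 22 minutes with an
interviewer, the full-length test is impractical for routine clinical
screening. This package implements a model-based route to a short form: keep
a small subset of reading items whose responses predict the full-length score
well enough that the short form can stand in for it.

## The scoring model

The short form is an integer-weighted linear rule over binary item responses
$C_j \in \{0, 1\}$:

$$ Y = b_0 + b_1 C_1 + b_2 C_2 + \dots + b_n C_n $$

All coefficients, including the intercept, are *trimmed to integers* so that
the form can be scored by hand with paper and pencil. Trimming is
round-half-away-from-zero (`trim = "truncate"` is available in
`search_config()` for sensitivity checks). Predicted scores are clipped to
$[0, 100]$ before level classification; for the packaged 20-item model,
whose attainable range is $[23, 95]$, the clip never binds.

## Sentence sets, not items

The reading items are cloze gaps inside sentences: removing one gap of a
sentence while keeping another would destroy the sentence's meaning. The
atomic unit of selection is therefore the *sentence set* — a maximal run of
consecutive reading items forming one sentence. `group_items()` validates
that the sets partition the reading items and are contiguous in
administration order. For the packaged 67-item bank there are 19 sets (5 of
size 1, 7 of size 2, 1 of size 3, 3 of size 4, 2 of size 5, 1 of size 6).
The six sets that compose the packaged short-form model are fixed by its
published coefficients; the boundaries of the other 13 sets are not public,
so the bank reconstructs them to match the published size distribution and
the contiguity constraint. They are a fixture convention: analyses that
depend on the exact boundaries of the non-selected sets should treat them as
synthetic.

## The search

`exhaustive_search()` scans model sizes upward, starting from one item. At
each item count it enumerates *every* combination of sentence sets whose
sizes sum to that count (`enumerate_combinations()`, deterministic
lexicographic order), fits each by least squares, trims to integers, and
evaluates it with leave-one-out cross-validation: each participant is
predicted by an integer-trimmed model fitted to the other $n - 1$
participants. The pooled out-of-fold predictions give the model's RMSE and
its Pearson correlation $r$ with the full-length score. Within an item
count the winner is the combination with the highest pooled $r$; ties break
by lower RMSE, then fewer sets, then lexicographic set ids (the tie order is
a package convention — at equal $r$, less machinery is preferred). The scan
stops at the smallest item count whose winner reaches the quality goal
(default $r \ge 0.9$).

Two quality conditions drive the default configuration: the correlation
threshold of 0.9, and the preference for a short form with *no numeracy
items*, because numeracy administration requires an interviewer. The first
pass therefore searches reading sets only; a fallback pass that admits
numeracy items (as singleton sets) runs only if no reading-only model of any
size meets the goal, and is recorded in `pass_used`.

### Reported coefficients

Per fold the float least-squares coefficients are retained; the final
model's parameters are the per-fold coefficient *means*, trimmed to integers
once at the end. Trimming each fold first and then averaging would generally
produce non-integer means, which would defeat hand-scoring — so
trim-after-mean is used.

### Complexity and the PRESS screen

The 19-set bank yields on the order of $10^5$ set combinations across model
sizes, each nominally requiring an $n$-fold LOOCV with integer trimming.
The default two-stage mode first screens every combination at an item count
with the closed-form leave-one-out error of the float fit — the PRESS
statistic, computed from leverage values $h_{ii}$ as
$\mathrm{press}_i = e_i / (1 - h_{ii})$ — and runs the exact
integer-trimmed LOOCV only on the best `screen_top = 50` candidates per
item count. PRESS is exact for the float model and differs from the integer
LOOCV only through trimming, which perturbs each coefficient by at most
0.5, so the float ranking is a faithful preselector. `search_config(exact =
TRUE)` disables the screen; the test suite checks that both modes select
identical winners on the packaged synthetic instances.

### Numerical conventions

* **Rank deficiency.** A training fold can contain a constant item column
  (everyone correct or everyone incorrect). Dropping the column would change
  the coefficient vector's length across folds, so degenerate designs are
  solved with the Moore–Penrose pseudo-inverse and flagged
  (`rank_deficient`), keeping shapes fixed.
* **Fold feasibility.** LOOCV requires each fold to have more rows than
  predictors; the scan caps the model size at $n - 2$ items.
* **Undefined correlations.** If pooled predictions are constant, $r$ is
  undefined; such a candidate ranks below any candidate with a defined $r$.
* **Determinism.** The search contains no randomness: identical inputs and
  configuration give identical results.

## Scoring conventions

* **Full-length score.** Reading items score 1 point each (50 items = 50
  points); the numeracy raw count is rescaled by $50/17$ and rounded
  half-up, making the parts worth 50 points each on the 0–100 scale. The
  equal-halves convention follows the original instrument's design; the
  rescaling rule and the half-up rounding are package conventions (the
  published account does not state them), chosen so each part contributes
  integer points.
* **Administration time.** Full parts take 12 (reading) and 10 (numeracy)
  minutes; a partial part is prorated and rounded *up* to whole minutes:
  $\lceil 12 n_R / 50 \rceil + \lceil 10 n_N / 17 \rceil$. Ceiling
  proration is the one rule that reproduces all four published times (22,
  12, 9, 5 minutes) simultaneously.
* **Accuracy rounding.** One-vs-rest accuracies are reported as whole
  percents, rounded half-up; this reproduces the published 92/80/88 from
  the published confusion matrix (145/158 = 91.77 → 92, 126/158 = 79.75 →
  80, 139/158 = 87.97 → 88).
* **Correlation strength bands.** The conventional bands on $|r|$ overlap at
  their printed edges (0–0.2, 0.2–0.5, 0.5–1); this package treats lower
  bounds as inclusive, so $|r| = 0.2$ is "medium" and $|r| = 0.5$ is "high".
* **Pearson CI.** The 95% interval uses the Fisher $z$ transform with the
  normal quantile 1.96 — the standard construction; the published account
  does not name its method.

## The synthetic cohort generator

Item-level data for the development cohort (n = 158 Danish COPD patients)
are not public, so the package ships a generator that emulates its
structure. `simulate_cohort()` draws a unidimensional latent literacy trait
$\theta_i \sim N(\mu_\theta, \sigma_\theta^2)$ and binary responses from a
two-parameter logistic (2PL) model,

$$ P(C_{ij} = 1) = \mathrm{logistic}\!\left(a_j (\theta_i - b_j)\right), $$

with discrimination $a_j > 0$ and difficulty $b_j$. Reading difficulties
are constrained non-decreasing in administration position, mirroring the
instrument's ordering of items by readability difficulty. The 2PL is the
simplest standard mechanism that produces unidimensional,
difficulty-ordered binary data; numeracy items share the same trait.

`default_danish_config()` fixes $a_j = 1.2$ for all items, part-wise
difficulties evenly spaced on $[-3, 1.5]$, and $\theta \sim N(0.65,
1.3^2)$. These values were calibrated once, by a coarse numeric sweep,
against the three published cohort marginals — full-score mean 71.6, SD
18.7, and level mix 25/21/54% — and then frozen; at large $n$ the
configuration gives mean ≈ 71.8, SD ≈ 19.3 and mix ≈ 25/24/51%. Only those
marginals constrain the calibration: the item-level parameters are a
modelling choice, not estimates of the real items.

What passing tests on such cohorts show — and what they do not: the
generator produces the statistical structure the method *assumes*
(unidimensional trait, difficulty-ordered binary items, realistic score
marginals), so tests demonstrate that the pipeline recovers planted signal
and reproduces published arithmetic under those assumptions. Real response
data can violate them (multidimensionality, guessing, local dependence
between gaps of one sentence beyond set membership, differential item
functioning), and nothing in the synthetic results speaks to robustness
against that.

### Planted-signal recovery instances

Recovery tests use a deliberately stark toy bank: 10 reading items in 5
sets of 2, where two middle sets carry all the discrimination ($a = 1.4$)
and the outer sets are nearly deterministic ($a = 0.1$ at difficulties
$\pm 40$, so background items are almost always correct or almost always
wrong). The full-length score is then driven by the planted items, and the
search should select exactly the planted sets. Placing the planted sets at
intermediate difficulty is not cosmetic: a planted item that everyone
answers correctly carries no variance and no signal, and background items
near $p = 0.5$ would inject noise into the full score that no reading
subset could explain. With this instance the winning combination contains
both planted sets, at $r \ge 0.9$, in 20 of 20 test seeds (the suite
requires at least 18).

## Problem sizes in the test suite

The suite favours instances small enough to re-derive by brute force:
oracle-equivalence tests enumerate the full power set of a 5-set bank with
an independently coded `lm()`-based LOOCV (n = 45–60); recovery runs 20
seeds at n = 120; generator calibration averages 50 replicates at the
development-cohort size n = 158. The full 19-set, n = 158 search is
exercised through the screened mode and documented in the README; its
exhaustive enumeration is the use case the PRESS screen exists for.

## Known limitations

* The reconstructed 13 set boundaries in the packaged bank are a
  convention; only the six selected sets are authoritative.
* The generator is unidimensional 2PL without guessing (no 3PL) and models
  no within-sentence local dependence.
* The comparison module's reference correlations (0.90 for the S-TOFHLA
  mirror and the derived short form, 0.85 for the prose-only mirror) are
  development-sample values reported for annotation; they are not expected
  values on synthetic cohorts and are never asserted by tests.
* The search is exhaustive by design; greedy or regularized selection is
  out of scope, as are non-linear classifiers.
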