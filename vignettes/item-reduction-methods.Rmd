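---
title: "Methods: random-forest item reduction for ordinal diagnostic instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-forest item reduction for ordinal diagnostic instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gold-standard diagnostic instruments for autism spectrum disorder — a
clinician-administered behavioral observation (ADOS, 28–29 ordinal items per
module) and a semi-structured caregiver interview (ADI-R) — are long and
expensive to administer. A recurring question is how much of their
discriminative power is carried by a small subset of items: which behaviors
are most indicative, and how few items suffice before classification
performance against a best-estimate clinical diagnosis (ASD vs. non-ASD)
degrades measurably.

`itemforest` implements that question as a reusable, fully seeded pipeline:

1. **Ranking.** A random forest is fit on a development portion of the
   cohort, and every item receives a permutation importance — the mean
   decrease in out-of-bag accuracy when the item's column is permuted.
2. **Stepwise reduced models.** For each prefix of the ranking
   (`k = 1..N` items), forests are trained under 20-fold cross-validation
   on the development portion (95% train / 5% test per fold).
3. **Validation and scoring.** Each prefix model is refit on the whole
   development portion and evaluated on a 25% held-out validation set; the
   model is scored by `w1 * AUC + w2 * complexity(k)` with `w1 = 0.35`,
   `w2 = 0.65`, weighting simplicity over accuracy 2:1. The argmax is the
   *optimal* model (ties go to the smaller `k`).
4. **Equivalence testing.** Each reduced model's validation predictions are
   compared with the full-feature model's by McNemar's test on the
   discordant counts; the smallest `k` with `p >= alpha` (default 0.05) is
   the *minimal* model.

Because the motivating clinical records are confidential, the package ships
a synthetic cohort generator so every stage is testable and calibratable
end to end, and the two instrument universes (ADOS + ADI-R combined vs.
ADOS alone) can be compared on identical subjects and splits.

## The synthetic cohort model

Each item is a proportional-odds (ordered-logit) variable with `n_levels`
ordinal codes `0..n_levels-1`. Baseline cutpoints are chosen so the non-ASD
group's code distribution is uniform; the ASD group draws from the same
cutpoints with its latent location shifted by the item's `shift`
(`P(Y <= j | ASD) = plogis(c_j - shift)`), moving mass toward higher codes.
One number per item therefore controls its discriminability, and
`ordinal_item_auc()` gives the implied population AUC in closed form
(shift 0 → 0.5; shift 1.5 at three levels → ≈ 0.70; shift 2 → ≈ 0.74).
Draws are independent across subjects and items given the seed.

The benchmark cohort (`default_cohort_spec()`) has 250 subjects per group
and 60 items — 29 "ADOS" and 31 "ADI-R" — of which 10 (5 per instrument)
are informative at shift 1.5. These sizes mirror a realistic single-module
clinical sample (a few hundred children per group, a minority of items
truly discriminative, per-item effects in the AUC ≈ 0.7 range) while
keeping repeated seeded runs desk-scale. Codes default to three levels,
matching the 0/1/2 coding convention of clinical item algorithms.
`adi_missing_fraction` removes the entire ADI-R block for a Bernoulli
selection of subjects — all-or-none per subject, since in practice the
interview either happened or did not — which reproduces the situation where
only an interview subset enters the combined analysis.

**What the generator does not emulate:** inter-item correlation beyond the
shared class label, rater and site effects, administrative codes (7/8) and
item-algorithm recodings, age or language-level structure, and any
particular real instrument's marginal distributions. Passing recovery and
calibration tests on these cohorts therefore demonstrates that the
*pipeline* behaves correctly under known signal, not that any specific
item subset generalizes to clinical data.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `validation_fraction` | 0.25 | class-stratified held-out fraction, never seen by ranking or training |
| `n_folds` | 20 | CV folds over the development portion (each test set ≈ 5%) |
| `w1`, `w2` | 0.35, 0.65 | weights on validation AUC and complexity |
| `alpha` | 0.05 | McNemar level defining the minimal model |
| `n_trees` | 500 | trees per forest |
| `features_per_split` | `"sqrt"` | candidate features per split (square-root rule) |
| `min_leaf` | 1 | terminal node size |
| `importance_repeats` | 5 | independent permutations averaged per item |
| `threshold` | 0.5 | ASD call when the vote fraction reaches it |

Forest hyperparameters follow common random-forest practice and are fully
config-exposed; none of them is critical to the ranking at these problem
sizes.

## Numerical and design choices

- **AUC** is the midrank (tie-aware) two-sample statistic. Vote fractions
  over a few hundred trees are heavily tied, so midranks are essential;
  the AUC is invariant under monotone transforms of the score.
- **Youden's J** is computed as `sensitivity + specificity - 1` by
  definition, always.
- **McNemar's test** defaults to the continuity-corrected chi-square when
  `min(b, c) < 25` and the plain chi-square otherwise, with an exact
  two-sided binomial option. The corrected statistic is clamped at zero
  when `b = c` so the correction can never exceed the uncorrected value,
  matching `stats::mcnemar.test`. With no discordant pairs the statistic
  is 0 and `p = 1`.
- **Complexity normalization.** The weighted score needs the feature count
  mapped onto the AUC scale. The default `linear_inverse` is
  `1 - (k - 1)/(N - 1)` (exactly 1 at `k = 1`, 0 at `k = N`);
  `rank_based`, `(N - k)/N`, is available as a flatter alternative. Both
  decrease strictly in `k`, so at equal AUC the simpler model always wins.
- **Importance** is computed on out-of-bag subjects of the development
  portion only: per tree, baseline OOB accuracy minus OOB accuracy after
  permuting the feature's column, averaged over trees and
  `importance_repeats` permutations. Ties in the ranking are broken by
  input item order, making the total order deterministic.
- **Validation predictions come from a single refit** on the full
  development portion rather than fold-averaged voting — the simplest
  model consistent with evaluating on data unseen during training.
- **The ranking is computed once on the development portion**, not
  re-derived per fold. The fold-level test metrics therefore carry some
  selection optimism (the fold test subjects participated in the ranking);
  the held-out validation metrics do not, which is why the weighted score
  and the McNemar comparisons use validation quantities.
- **Complete-case policy.** Subjects missing any item of the active
  universe are dropped before splitting. For the paired universe
  comparison (`compare_universes()`) completeness is enforced over the
  *combined* universe, so both universes run on identical subjects and one
  shared validation split, making the comparison paired; the alternative —
  each universe on its own available subset — is reachable by running the
  universes separately.
- **Degenerate inputs** (one-class training sets, folds whose test set
  loses a class, items entirely missing in one class) raise explicit
  errors naming the stage or fold rather than propagating `NaN`s.
- **CV scheme.** The 20 folds are a true partition by default (every
  development subject tested exactly once); a resampling variant (20
  independent stratified 95/5 draws) is available by flag since either
  reading of "20-fold cross-validation with 95/5 splits" is defensible.

## A documented tension in the weighted score

With `w1 = 0.35`, `w2 = 0.65` and either normalization, adding one feature
at `N = 60` costs about `0.65/59 ≈ 0.011` score units, so it must buy
roughly `0.031` AUC to be worthwhile. On any cohort whose AUC curve rises
steeply and then plateaus — including the benchmark cohort, where marginal
AUC gains past the first few items are below 0.03 — the argmax lands on
very small models (`k ≈ 3–6`), typically below the number of truly
informative items. This is a property of the scoring rule itself, not of
the forest or the ranking; published optimal models in the tens of
features cannot be recovered from this formula with any complexity scaling
implemented here. The package keeps the rule as specified, exposes both
normalizations, and reports the full `k → score` curve so users can see
the trade-off rather than trusting a single argmax. The McNemar-based
minimal model is unaffected by this issue.

## Calibration experiments and problem sizes

The test suite runs two seeded experiments on the benchmark cohorts, with
100-tree forests (rankings and validation scores are stable at that size
for 500-subject cohorts, and the designs stay desk-scale):

- **Recovery** (20 seeds, full `k` curve): how often the top-10 ranking
  captures at least 8 of the 10 informative items, where the optimal and
  minimal models land, and whether validation AUC at `k = 10` has already
  reached the full-model level (stagnation).
- **Null calibration** (200 seeds, all shifts 0): the full model's
  validation AUC distribution around 0.5, and the McNemar false-rejection
  rate for the 1-feature model against the full model, which should match
  `alpha`.

One caveat is worth stating precisely: with 124 validation subjects the
rank-AUC of chance-level scores has standard deviation
`sqrt((n1 + n2 + 1)/(12 n1 n2)) ≈ 0.05`, so even a perfectly calibrated
null pipeline leaves the interval `[0.45, 0.55]` in roughly a third of
runs. Tight null-AUC bands at this validation size cannot be met by any
correct implementation; the McNemar size, which aggregates over subjects
rather than ranks, is the sharper calibration check at this scale.

## Limitations

- The exclusive learner is the random forest; no alternative classifiers,
  no non-prefix subset search, and no per-fold re-ranking are provided.
- No confidence intervals for AUC and no DeLong-style AUC comparisons;
  model equivalence is assessed only through McNemar's test on class
  calls.
- Synthetic cohorts are independence-model idealizations (see above);
  conclusions about specific clinical item subsets require real data.
- Importance is permutation-based mean decrease in accuracy only; impurity
  and conditional importances are out of scope.
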