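---
title: "Methods: constructing and validating a charitable-food nutrition index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing and validating a charitable-food nutrition index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfni)
```

## The measurement problem

Food banks and pantries increasingly rank individual foods with a stoplight
scheme: green (choose often), yellow (choose sometimes), red (choose rarely),
assigned within 11 food categories from three per-serving nutrients of concern
— saturated fat, sodium and added sugar. The scheme ranks *items*, but says
nothing about how to summarise an *assortment* (a client's cart, a pantry's
inventory). The gold-standard assortment measure, the Healthy Eating Index
2015 (HEI-2015), needs full nutrient profiles and is impractical in
low-resource settings.

This package implements the bridge between the two: it learns, from carts that
have both tier percentages and HEI scores, a weighted combination of the
percent-by-weight of green, yellow and red food that best predicts HEI, and
rescales it to a 0–100 score — the Charitable Food Nutrition Index (CFNI).

## Tier ranking

`rank_items()` applies, per category, inclusive cutoffs `green_max` /
`yellow_max` to each of the three nutrients and takes the **worst** nutrient
as the item tier: one disqualifying nutrient decides the rank, as in
SWAP-style systems. Inclusive comparison (`value <= green_max` is green)
follows the "no more than" phrasing conventional in nutrient guidelines; if a
transcribed guideline table needs a strict cutoff for some nutrient the config
can encode it by nudging the boundary, and the choice is documented here so it
can be revisited per nutrient.

Condiments/cooking staples and miscellaneous foods are never ranked. They are
removed from the dataset before *any* cart-level measure — they appear in
neither the numerator nor the denominator of the tier percentages, and they
are excluded from HEI scoring as well. A cart consisting solely of not-ranked
food is degenerate and is dropped with a warning.

Cutoff values are configuration data, not code. The shipped file
`her-thresholds-synthetic.yaml` is a clearly-labelled synthetic stand-in
(FDA low/moderate claim levels) so the pipeline runs out of the box; users
ranking real inventory should transcribe the published guideline tables into
the same YAML layout. All unit tests that depend on concrete cutoffs use an
explicit toy configuration, so the engine's correctness does not rest on the
shipped numbers.

## HEI-2015 scoring

`score_carts()` computes, per cart, ratio-of-totals densities — constituent
totals are summed over the cart first and divided by total energy, never
averaged per item — and scores 13 components piecewise-linearly against
configurable standards (`hei2015-standards.yaml`): nine adequacy components
(amount per 1000 kcal, plus the (MUFA+PUFA)/SFA fatty-acid ratio) and four
moderation components (refined grains and sodium per 1000 kcal; added sugars
and saturated fat as percent of energy, converted at 4 kcal/g and 9 kcal/g
respectively — constants stated here because they are conventions of the
index, not inputs). Component points sum to the 0–100 total; a configuration
whose maxima do not sum to 100 is rejected.

Degenerate inputs: zero cart energy makes every density undefined and raises
an error; a zero-SFA cart scores full fatty-acid points when any unsaturated
fat is present (the limit of the ratio) and zero points when the cart has no
fat at all (no adequacy evidence).

## Weight learning and the index transform

With tier percentages summing to 100, the three variables are collinear, so
the model uses %green and %red only:

* **Model 1** — ridge regression, penalty chosen by an information criterion.
  The criterion is `n log(RSS/n) + w · df_eff` with
  `df_eff = Σ dᵢ²/(dᵢ²+λ) + 1` (trace of the ridge hat matrix; intercept
  unpenalised). BIC (`w = log n`) is the default — of the two standard
  criteria it selects the stronger shrinkage, matching the intended
  conservative character of this variant — with AIC selectable.
* **Model 2** — ridge with the penalty chosen by inner 10-fold
  cross-validation (seeded; distinct from the 5-fold *evaluation* CV).
* **Model 3** — OLS via `lm()`.

Ridge is solved in closed form on centered, unit-SD predictors with an
unpenalised intercept, and coefficients are mapped back to the raw percentage
scale; `λ = 0` reproduces OLS to machine precision. The penalty grid is 101
log-spaced points in `[1e-4, 1e4]`; ties in either selection rule break toward
the larger penalty (more shrinkage).

`to_index_formula()` rewrites the fitted plane `c + b_G·G + b_R·R` as a
function of all three tiers using `Y = 100 − G − R`:

> weight_green = c/100 + b_G,  weight_yellow = c/100,  weight_red = c/100 + b_R

and rescales with the **theoretical** simplex anchors — `offset = 100·min(w)`,
`scale = 100·(max(w) − min(w))` — so an all-green cart scores exactly 100 and
an all-red cart exactly 0. Sample-based rescaling (anchoring to the observed
min/max) would change the reported mean of the index but not its correlations;
the theoretical anchoring is used because it makes the formula portable to new
assortments without reference data. The rescaling is affine, so the index
ranks carts identically to predicted HEI and correlations with HEI are
unchanged — which is why the cross-validated correlation below is insensitive
to the anchoring choice.

Formula constants are printed at 4 decimals by convention; arithmetic keeps
full precision.

## Validation machinery

* `pearson_r()` — sample correlation with the two-sided t-transform p-value.
* `assign_quintiles()` — stable rank-based split; remainders go to the
  lowest-index quintiles (503 carts split 101/101/101/100/100); ties keep
  input order (no tie rule is standard, so the simplest deterministic one is
  used).
* `quintile_profile()` — per-quintile tier means and a linear trend test
  regressing each tier percentage on the quintile index as numeric 1–5
  (category-coded contrasts are the alternative; the numeric regressor is the
  conventional "p for trend"). P-values are unadjusted.
* `kfold_cv_correlation()` — the headline estimate: a seeded equal partition
  (sizes within 1, e.g. the multiset {101, 101, 101, 100, 100} at n = 503);
  per fold, the chosen model is fitted on the other folds, transformed to an
  index formula, and the Pearson correlation between held-out index and
  held-out HEI is recorded. The mean of the k correlations estimates the
  index–HEI correlation in a new sample; the SD over folds uses the sample
  (n−1) formula.

## The synthetic-data generator

No cart-level dataset is distributed, so the package carries two simulators
whose defaults are fixed once to the study conditions and not revisited.

**Composition level** (`generate_compositions()`): 503 carts; (G, R) from a
bivariate normal with means (50.1, 23.9) and SDs (14.1, 12.4);
`Y = 100 − G − R`; draws with any component outside [0, 100] rejected
(rejection, not clipping, to preserve moments);
`HEI = 56.72 + 0.270·G − 0.278·R + ε`, `ε ~ N(0, noise_sd)`, truncated to
[0, 100] because the index is bounded. The OLS plane is used as the generating
truth because OLS is unbiased for it; the ridge variants are evaluated against
it. Two parameters are not identifiable from marginal summaries and are set by
`calibrate_generator()` moment matching:

* `corr(G, R) ≈ −0.690`, chosen so the generating plane's variance equals
  `(0.585 × 11.4)²` — i.e. the plane explains the target signal fraction of an
  HEI SD of 11.4. A symmetric Dirichlet cannot reach this dependence (it tops
  out near −0.56), which is why the truncated-normal construction is used.
* `noise_sd = 11.4 × sqrt(1 − 0.585²) ≈ 9.246`.

The truncation steps bias the realised moments slightly (the red margin sits
1.9 SDs from zero, so roughly 2–3% of raw draws are rejected); Monte-Carlo
verification at n = 50 000 shows the realised predictor–HEI correlation within
±0.03 of the target, and the realised cross-validated correlation at n = 503
runs ≈ 0.02 below the nominal 0.585 for the same reason. HEI clipping touches
under 1% of draws. These are properties of the generator, asserted in the
test suite.

**Item level** (`generate_catalog_and_carts()`): carts of 5–80 items (item
count normal around 42 — the average pantry visit is roughly forty items —
rounded and truncated), categories drawn with fruit-and-vegetable-heavy
weights, lognormal weights, gamma per-serving nutrients around per-category
means, and constituent totals proportional to weight with category-flavoured
densities. This level exists to exercise the ranker and scorer end to end —
every category occurs, including not-ranked ones, so exclusion logic is always
hit. It does **not** model real food co-occurrence, seasonality, brand-level
nutrient variation, or the empirical tier–HEI dependence; passing end-to-end
tests on it demonstrates mechanical correctness of the pipeline, not
real-data validity of the index.

## Problem sizes and determinism

The test suite simulates at the study scale where the property depends on it
(n = 503 for fold sizes and moment checks; 200 replicates for the OLS
confidence-interval coverage check; 50 000 draws for the calibration
verification) and at 40–300 carts elsewhere; everything is seeded through
`withr::with_seed`, so runs are reproducible, and result files serialize
byte-identically (stable key order, 6 significant digits, embedded seed and
configuration digest).

## Known limitations

* The shipped tier thresholds are synthetic stand-ins, not the published
  guideline values; conclusions about any real inventory require
  transcription.
* The HEI engine implements the published 13-component HEI-2015 scoring; the
  upstream 28-ratio constituent bookkeeping of nutrition software is
  collapsed into the 13 component densities, with the constituent mapping
  left to configuration.
* The exact software behaviour behind the original ridge fits is not fully
  specified (information criterion, grid, standardization), so fitted
  coefficients on any given dataset are method-faithful rather than
  bit-reproducible; the index transform and its anchors, by contrast, are
  exact algebra.
* Index means under theoretical anchoring are not comparable to means
  reported under sample-based rescaling; correlations are.
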