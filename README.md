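# cfni — a Charitable Food Nutrition Index for stoplight tier-ranked food assortments

Charitable food agencies increasingly rank individual foods with a
green / yellow / red stoplight scheme driven by per-serving saturated fat,
sodium and added sugar within 11 food categories. The scheme ranks items; it
gives no single score for an *assortment* — a food-pantry client's cart or a
pantry's inventory. The gold-standard assortment measure, the Healthy Eating
Index 2015 (HEI-2015), needs full nutrient profiles and is impractical in
low-resource settings.

`cfni` closes that gap. From carts that carry both tier percentages and HEI
scores it learns weights for the percent-by-weight of green, yellow and red
food that best predict HEI, and rescales the fit to a 0–100 index:

```
CFNI = (((w_G · %Green) + (w_Y · %Yellow) + (w_R · %Red)) − offset) / scale × 100
```

where, for a fitted plane `HEI ≈ c + b_G·%Green + b_R·%Red` on compositions
summing to 100, `w_G = c/100 + b_G`, `w_Y = c/100`, `w_R = c/100 + b_R`,
`offset = 100·min(w)` and `scale = 100·(max(w) − min(w))` — so a 100%-green
cart scores exactly 100 and a 100%-red cart exactly 0.

The package provides the full pipeline:

* **`rank_items()` / `summarize_carts()`** — stoplight tier ranking from a
  YAML threshold configuration (worst nutrient decides; condiments/cooking
  staples and miscellaneous foods are excluded from all cart measures).
* **`score_carts()`** — a configuration-driven HEI-2015 engine:
  ratio-of-totals densities, 13 components scored piecewise-linearly against
  minimum/maximum standards.
* **`fit_index_model()`** — ridge regression with the penalty from an
  information criterion (model 1) or inner cross-validation (model 2), or OLS
  (model 3), predicting HEI from %green and %red.
* **`to_index_formula()` / `cfni_score()`** — the three-tier 0–100 index.
* **`kfold_cv_correlation()`, `quintile_profile()`, `pearson_r()`** —
  validation: held-out index-vs-HEI correlation, quintile trend tests.
* **`generate_compositions()` / `generate_catalog_and_carts()`** — seeded,
  moment-calibrated synthetic cart generators.
* **`run_pipeline()`** — one call from cart-item CSV (or simulation) to a
  deterministic JSON report; a thin CLI lives in `inst/cli/cfni.R`.

## Worked example

Simulate 503 carts at the generator's calibrated defaults, fit model 1, build
the index and cross-validate it:

```r
library(cfni)

comp <- generate_compositions(composition_params(seed = 1))
head(round(comp[, -1], 2), 3)
#>   pct_green pct_yellow pct_red   hei
#> 1     41.27      22.19   36.54 61.56
#> 2     52.69      42.15    5.16 66.60
#> 3     38.32      41.83   19.85 69.18

fit <- fit_index_model(comp, comp$hei, method = "model1_ridge_ic")
fit
#> CFNI weight model [model1_ridge_ic]
#>   HEI ~ 60.7601 + 0.2123 * pct_green -0.3239 * pct_red
#>   ridge penalty lambda = 47.863

f <- to_index_formula(fit)
f
#> CFNI = (((0.8199*Green) + (0.6076*Yellow) + (0.2837*Red)) - 28.37) / 53.61 * 100

cfni_score(f, c(100, 0, 0)); cfni_score(f, c(0, 0, 100))
#> [1] 100
#> [1] 0

kfold_cv_correlation(comp, comp$hei, method = "model1_ridge_ic", k = 5, seed = 1)
#> 5-fold CV correlation [model1_ridge_ic]
#>   fold 1 (n = 101): r = 0.5549
#>   fold 2 (n = 101): r = 0.5401
#>   fold 3 (n = 101): r = 0.5789
#>   fold 4 (n = 100): r = 0.5897
#>   fold 5 (n = 100): r = 0.5943
#>   mean = 0.5716, SD = 0.0233
```

The fitted weights order green > yellow > red, the index is anchored at 100
for all-green and 0 for all-red carts, and the mean held-out correlation
(~0.57 here) estimates how well the index tracks HEI in a new sample of
carts. With real data, replace the simulated frame by
`read_cart_table("items.csv")` + `summarize_carts()` + `score_carts()`; the
shipped tier thresholds are synthetic stand-ins, so transcribe your guideline
tables first (see the methods vignette, `vignettes/cfni-methods.Rmd`).

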