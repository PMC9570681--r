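#' The 11 HER food categories
#'
#' Category names used by the tier-ranking configuration and the cart-item
#' table. Condiments/cooking staples and miscellaneous items are never
#' tier-ranked.
#'
#' @export
her_categories <- c(
  "fruits_vegetables", "grains", "protein", "dairy",
  "non_dairy_alternatives", "beverages", "mixed_dishes", "snacks",
  "desserts", "condiments_cooking_staples", "miscellaneous"
)

#' Dietary constituent fields carried per item
#'
#' Whole-item totals (not per serving). Units: energy kcal; fruit, vegetable
#' and dairy groups cup-equivalents; grain and protein groups
#' ounce-equivalents; fatty acids and added sugar grams; sodium milligrams.
#'
#' @export
hei_constituents <- c(
  "energy", "total_fruit", "whole_fruit", "total_veg", "greens_beans",
  "dairy", "whole_grain", "refined_grain", "total_protein",
  "seafood_plant_protein", "mufa", "pufa", "sfa", "sodium", "added_sugar"
)

# Stop with a classed condition so callers (and the CLI) can distinguish
# validation problems (exit code 2) from programming errors.
cfni_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "cfni_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)

# %||% for default arguments
`%||%` <- function(a, b) if (is.null(a)) b else a
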