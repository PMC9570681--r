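# Toy configurations with hand-checkable numbers, built in code.

# Single ranked category plus the two never-ranked ones.
toy_thresholds <- function() {
  as_tier_thresholds(list(
    grains = list(
      ranked = TRUE,
      sat_fat = list(green_max = 2, yellow_max = 5),
      sodium = list(green_max = 230, yellow_max = 480),
      added_sugar = list(green_max = 6, yellow_max = 12)
    ),
    condiments_cooking_staples = list(ranked = FALSE),
    miscellaneous = list(ranked = FALSE)
  ))
}

# All 11 categories: nine ranked with common cutoffs, two not ranked.
toy_thresholds_full <- function() {
  ranked <- setdiff(her_categories,
                    c("condiments_cooking_staples", "miscellaneous"))
  blocks <- lapply(ranked, function(cat) list(
    ranked = TRUE,
    sat_fat = list(green_max = 2, yellow_max = 5),
    sodium = list(green_max = 230, yellow_max = 480),
    added_sugar = list(green_max = 6, yellow_max = 12)))
  names(blocks) <- ranked
  blocks$condiments_cooking_staples <- list(ranked = FALSE)
  blocks$miscellaneous <- list(ranked = FALSE)
  as_tier_thresholds(blocks)
}

# Item builder: green-by-default grains item, overridable.
make_item <- function(cart_id = "A", item_id = "i1", category = "grains",
                      weight_lb = 1, sat_fat = 0, sodium = 0, sugar = 0,
                      constituents = NULL) {
  row <- data.frame(cart_id = cart_id, item_id = item_id, category = category,
                    weight_lb = weight_lb, sat_fat_g_serv = sat_fat,
                    sodium_mg_serv = sodium, added_sugar_g_serv = sugar,
                    stringsAsFactors = FALSE)
  cons <- stats::setNames(as.list(rep(0, length(hei_constituents))),
                          hei_constituents)
  for (nm in names(constituents)) cons[[nm]] <- constituents[[nm]]
  cbind(row, as.data.frame(cons))
}

make_cart <- function(...) do.call(rbind, list(...))

# Constituent totals vector (whole cart), defaulting to zeros + given energy.
make_totals <- function(energy = 1000, ...) {
  tot <- stats::setNames(rep(0, length(hei_constituents)), hei_constituents)
  tot["energy"] <- energy
  extra <- list(...)
  for (nm in names(extra)) tot[nm] <- extra[[nm]]
  tot
}

toy_moderation_standard <- function() {
  list(name = "added_sugars", max_points = 10, kind = "moderation",
       basis = "percent_of_energy", constituent = "added_sugar",
       kcal_per_gram = 4, standard_for_max = 6.5, standard_for_min = 26)
}

toy_adequacy_standard <- function() {
  list(name = "total_fruits", max_points = 5, kind = "adequacy",
       basis = "per_1000_kcal", constituent = "total_fruit",
       standard_for_max = 0.8, standard_for_min = 0)
}

# Items (incl. constituents) for a cart meeting every adequacy maximum with
# zero moderation constituents -> HEI total 100 under the shipped standards.
perfect_cart <- function(cart_id = "P") {
  make_item(cart_id = cart_id, category = "fruits_vegetables",
            constituents = list(energy = 1000, total_fruit = 0.8,
                                whole_fruit = 0.4, total_veg = 1.1,
                                greens_beans = 0.2, dairy = 1.3,
                                whole_grain = 1.5, total_protein = 2.5,
                                seafood_plant_protein = 0.8,
                                mufa = 10, pufa = 10))
}

# Cart with no adequacy constituents and every moderation density at or
# beyond the zero-point standard -> HEI total 0.
worst_cart <- function(cart_id = "W") {
  make_item(cart_id = cart_id, category = "desserts",
            constituents = list(energy = 1000, refined_grain = 4.3,
                                sodium = 2000, added_sugar = 65,
                                sfa = 1000 * 0.16 / 9))
}
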