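#' Tier levels
#'
#' Severity-ordered tier labels. `green < yellow < red`; `not_ranked` marks
#' items excluded from ranking altogether.
#' @export
tier_levels <- c("green", "yellow", "red", "not_ranked")

tier_for_value <- function(value, green_max, yellow_max) {
  # inclusive cutoffs: "no more than" phrasing of nutrient guidelines
  ifelse(value <= green_max, 1L, ifelse(value <= yellow_max, 2L, 3L))
}

#' Assign a stoplight tier to one food item
#'
#' An item in a ranked category gets, for each thresholded nutrient, green if
#' its per-serving value is at or below `green_max`, yellow if at or below
#' `yellow_max`, red otherwise; the item tier is the *worst* (most severe)
#' per-nutrient tier. One disqualifying nutrient therefore defines the rank,
#' as in SWAP-style stoplight systems. Items in unranked categories
#' (condiments/cooking staples, miscellaneous) are `not_ranked`.
#'
#' @param item a list or one-row data.frame with `category`,
#'   `sat_fat_g_serv`, `sodium_mg_serv`, `added_sugar_g_serv`.
#' @param thresholds a [as_tier_thresholds()] configuration covering
#'   `item$category`.
#' @return one of `"green"`, `"yellow"`, `"red"`, `"not_ranked"`.
#' @export
rank_item <- function(item, thresholds) {
  df <- as.data.frame(item[c("category", "sat_fat_g_serv", "sodium_mg_serv",
                             "added_sugar_g_serv")])
  rank_items(df, thresholds)
}

#' Assign tiers to a table of food items
#'
#' Vectorised form of [rank_item()].
#'
#' @param items data.frame with columns `category`, `sat_fat_g_serv`,
#'   `sodium_mg_serv`, `added_sugar_g_serv` (one row per item).
#' @param thresholds a `cfni_thresholds` configuration.
#' @return character vector of tiers, aligned with `items` rows.
#' @export
rank_items <- function(items, thresholds) {
  thresholds <- as_tier_thresholds(thresholds)
  missing_cat <- setdiff(unique(as.character(items$category)), names(thresholds))
  if (length(missing_cat)) {
    cfni_stop(sprintf("no threshold configuration for category: %s",
                      paste(missing_cat, collapse = ", ")),
              "cfni_config_error")
  }
  nut_cols <- c(sat_fat = "sat_fat_g_serv", sodium = "sodium_mg_serv",
                added_sugar = "added_sugar_g_serv")
  out <- character(nrow(items))
  for (cat in unique(as.character(items$category))) {
    idx <- which(items$category == cat)
    blk <- thresholds[[cat]]
    if (!isTRUE(blk$ranked)) {
      out[idx] <- "not_ranked"
      next
    }
    worst <- rep(1L, length(idx))
    for (nut in names(nut_cols)) {
      th <- blk[[nut]]
      if (is.null(th)) next                     # no threshold for this nutrient
      sev <- tier_for_value(items[[nut_cols[[nut]]]][idx],
                            th$green_max, th$yellow_max)
      worst <- pmax(worst, sev)
    }
    out[idx] <- c("green", "yellow", "red")[worst]
  }
  out
}

#' Percent-by-weight tier summary of one cart
#'
#' Not-ranked items are removed before anything else is computed: they enter
#' neither the numerator nor the denominator, so the three percentages are
#' shares of *ranked* weight and sum to 100. A cart whose items are all
#' not-ranked is degenerate; it gets `NA` percentages, `ranked_weight` 0, and
#' a warning — downstream analyses drop such carts.
#'
#' @param cart data.frame of the cart's items (columns `cart_id`, `category`,
#'   `weight_lb`, nutrient columns as in [rank_items()]).
#' @param thresholds a `cfni_thresholds` configuration.
#' @return one-row data.frame: `cart_id`, `pct_green`, `pct_yellow`,
#'   `pct_red`, `ranked_weight`, `excluded_weight`.
#' @export
summarize_cart <- function(cart, thresholds) {
  if (nrow(cart) == 0) cfni_stop("cart is empty", "cfni_validation_error")
  tier <- rank_items(cart, thresholds)
  w <- cart$weight_lb
  ranked <- tier != "not_ranked"
  rw <- sum(w[ranked])
  ew <- sum(w[!ranked])
  if (rw <= 0) {
    warning(sprintf("cart '%s' contains only not-ranked food; excluded from analysis",
                    cart$cart_id[[1]]), call. = FALSE)
    return(data.frame(cart_id = cart$cart_id[[1]], pct_green = NA_real_,
                      pct_yellow = NA_real_, pct_red = NA_real_,
                      ranked_weight = 0, excluded_weight = ew,
                      stringsAsFactors = FALSE))
  }
  pct <- vapply(c("green", "yellow", "red"),
                function(tr) 100 * sum(w[tier == tr]) / rw, numeric(1))
  data.frame(cart_id = cart$cart_id[[1]], pct_green = pct[["green"]],
             pct_yellow = pct[["yellow"]], pct_red = pct[["red"]],
             ranked_weight = rw, excluded_weight = ew,
             stringsAsFactors = FALSE)
}

#' Tier summaries for every cart in an item table
#'
#' @param items data.frame of items for many carts (grouped by `cart_id`).
#' @param thresholds a `cfni_thresholds` configuration.
#' @param drop_degenerate drop carts with no ranked weight (default `TRUE`,
#'   with a warning per dropped cart).
#' @return data.frame of per-cart tier summaries, one row per (retained) cart,
#'   in first-appearance order of `cart_id`.
#' @export
summarize_carts <- function(items, thresholds, drop_degenerate = TRUE) {
  ids <- unique(items$cart_id)
  rows <- lapply(ids, function(id) {
    summarize_cart(items[items$cart_id == id, , drop = FALSE], thresholds)
  })
  out <- do.call(rbind, rows)
  if (drop_degenerate) out <- out[!is.na(out$pct_green), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collection-level tier summary
#'
#' Per-cart summaries plus unweighted means and sample standard deviations of
#' the three tier percentages across carts.
#'
#' @inheritParams summarize_carts
#' @return list with `summaries` (data.frame), `means` and `sds` (named
#'   numeric over pct_green/pct_yellow/pct_red), and `n_carts`.
#' @export
summarize_collection <- function(items, thresholds) {
  summaries <- summarize_carts(items, thresholds)
  if (nrow(summaries) == 0) {
    cfni_stop("all carts are degenerate (no ranked food)", "cfni_analysis_error")
  }
  cols <- c("pct_green", "pct_yellow", "pct_red")
  means <- vapply(summaries[cols], mean, numeric(1))
  sds <- vapply(summaries[cols], stats::sd, numeric(1))
  list(summaries = summaries, means = means, sds = sds,
       n_carts = nrow(summaries))
}
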