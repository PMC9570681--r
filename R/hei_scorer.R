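#' Validate an HEI component-standards configuration
#'
#' A standards set is a list of component blocks, each with `name`,
#' `max_points` (5 or 10), `kind` (`adequacy` or `moderation`), `basis`
#' (`per_1000_kcal`, `percent_of_energy` or `fatty_acid_ratio`), the
#' constituent it scores and the `standard_for_max` / `standard_for_min`
#' densities that earn full and zero points. For a complete index the
#' `max_points` must sum to 100 (checked by [score_cart()], not here, so toy
#' subsets can be used in unit tests).
#'
#' @param x list of component blocks, or a list with a single `components`
#'   element (the YAML layout).
#' @return object of class `cfni_standards` (a list of component blocks).
#' @export
as_hei_standards <- function(x) {
  if (inherits(x, "cfni_standards")) return(x)
  if (!is.null(x$components)) x <- x$components
  if (!is.list(x) || !length(x)) {
    cfni_stop("standards must be a non-empty list of component blocks",
              "cfni_config_error")
  }
  for (comp in x) {
    if (is.null(comp$name) || is.null(comp$max_points) || is.null(comp$kind) ||
        is.null(comp$basis)) {
      cfni_stop("each component needs name, max_points, kind, basis",
                "cfni_config_error")
    }
    if (!comp$max_points %in% c(5, 10)) {
      cfni_stop(sprintf("component '%s': max_points must be 5 or 10", comp$name),
                "cfni_config_error")
    }
    if (!comp$kind %in% c("adequacy", "moderation")) {
      cfni_stop(sprintf("component '%s': kind must be adequacy or moderation",
                        comp$name), "cfni_config_error")
    }
    if (!comp$basis %in% c("per_1000_kcal", "percent_of_energy",
                           "fatty_acid_ratio")) {
      cfni_stop(sprintf("component '%s': unknown basis '%s'", comp$name,
                        comp$basis), "cfni_config_error")
    }
    if (comp$basis != "fatty_acid_ratio" && is.null(comp$constituent)) {
      cfni_stop(sprintf("component '%s': missing constituent", comp$name),
                "cfni_config_error")
    }
    if (comp$kind == "moderation" &&
        !(comp$standard_for_max < comp$standard_for_min)) {
      cfni_stop(sprintf(
        "component '%s': moderation needs standard_for_max < standard_for_min",
        comp$name), "cfni_config_error")
    }
  }
  structure(x, class = "cfni_standards")
}

#' Read HEI component standards from YAML
#' @param path YAML file with a `components` list (see the shipped
#'   `hei2015-standards.yaml` for the layout).
#' @return a `cfni_standards` object.
#' @export
read_hei_standards <- function(path) {
  if (!file.exists(path)) {
    cfni_stop(sprintf("standards file not found: %s", path), "cfni_io_error")
  }
  as_hei_standards(yaml::read_yaml(path))
}

#' The HEI-2015 standards shipped with the package
#'
#' Thirteen components (total max points 100): nine adequacy components
#' (including the unsaturated-to-saturated fatty-acid ratio) and four
#' moderation components (refined grains, sodium, added sugars, saturated
#' fats), scored piecewise-linearly on energy-density bases.
#'
#' @return a `cfni_standards` object.
#' @export
default_hei_standards <- function() {
  read_hei_standards(
    system.file("extdata", "hei2015-standards.yaml", package = "cfni",
                mustWork = TRUE))
}

#' Sum dietary constituents over a cart
#'
#' Whole-cart totals: component-wise sums of the per-item constituent columns.
#' Densities are *ratios of totals* — they are computed from these sums by
#' [component_score()], never averaged per item. The cart is expected to have
#' been filtered of not-ranked items already (tier ranking removes them from
#' the dataset before any cart-level measure).
#'
#' @param cart data.frame of one cart's items with the [hei_constituents]
#'   columns.
#' @return named numeric vector over [hei_constituents].
#' @export
accumulate_constituents <- function(cart) {
  if (nrow(cart) == 0) {
    cfni_stop("cart has no items; HEI undefined", "cfni_validation_error")
  }
  missing <- setdiff(hei_constituents, names(cart))
  if (length(missing)) {
    cfni_stop(sprintf("missing constituent columns: %s",
                      paste(missing, collapse = ", ")), "cfni_schema_error")
  }
  totals <- vapply(hei_constituents, function(cc) sum(cart[[cc]]), numeric(1))
  if (totals[["energy"]] <= 0) {
    cfni_stop("cart energy total is zero; HEI densities undefined",
              "cfni_validation_error")
  }
  totals
}

hei_density <- function(totals, standard) {
  switch(standard$basis,
    per_1000_kcal = totals[[standard$constituent]] * 1000 / totals[["energy"]],
    percent_of_energy = totals[[standard$constituent]] *
      standard$kcal_per_gram * 100 / totals[["energy"]],
    fatty_acid_ratio = {
      unsat <- totals[["mufa"]] + totals[["pufa"]]
      if (totals[["sfa"]] > 0) unsat / totals[["sfa"]]
      else if (unsat > 0) Inf   # no saturated fat at all: ratio limit
      else NA_real_             # no fat of any kind: no adequacy evidence
    })
}

#' Score one HEI component
#'
#' Piecewise-linear scoring of a constituent density against a component
#' standard. Adequacy components earn `max_points` at or beyond
#' `standard_for_max` and 0 at or below `standard_for_min` (usually zero
#' intake), linear in between; moderation components earn `max_points` at or
#' below `standard_for_max` and 0 at or beyond `standard_for_min`. The result
#' is clamped to `[0, max_points]`.
#'
#' A fatty-acid ratio with zero saturated fat scores full points when any
#' unsaturated fat is present (the limit of the ratio) and zero when the cart
#' contains no fat at all.
#'
#' @param totals named constituent totals from [accumulate_constituents()].
#' @param standard one component block of a `cfni_standards` set.
#' @return points in `[0, max_points]`.
#' @export
component_score <- function(totals, standard) {
  d <- hei_density(totals, standard)
  mp <- standard$max_points
  if (is.na(d)) return(0)      # fat-free cart on the fatty-acid component
  if (standard$kind == "adequacy") {
    lo <- standard$standard_for_min %||% 0
    hi <- standard$standard_for_max
    raw <- mp * (d - lo) / (hi - lo)
  } else {
    hi <- standard$standard_for_max   # full-credit density
    lo <- standard$standard_for_min   # zero-credit density (hi < lo)
    raw <- mp * (lo - d) / (lo - hi)
  }
  min(max(raw, 0), mp)
}

#' HEI score of one cart
#'
#' Sums the 13 component scores into the 0-100 total. Only the total is used
#' downstream by the index model; the component breakdown is retained for
#' inspection and testing.
#'
#' @param cart data.frame of one cart's items (constituent columns), already
#'   filtered of not-ranked items.
#' @param standards a `cfni_standards` set whose `max_points` sum to 100.
#' @return list with `cart_id`, `component_scores` (named numeric) and
#'   `total`.
#' @export
score_cart <- function(cart, standards) {
  standards <- as_hei_standards(standards)
  mp <- vapply(standards, function(s) s$max_points, numeric(1))
  if (sum(mp) != 100) {
    cfni_stop(sprintf("component max_points sum to %g, not 100", sum(mp)),
              "cfni_config_error")
  }
  totals <- accumulate_constituents(cart)
  comp <- vapply(standards, function(s) component_score(totals, s), numeric(1))
  names(comp) <- vapply(standards, `[[`, character(1), "name")
  list(cart_id = if ("cart_id" %in% names(cart)) cart$cart_id[[1]] else NA,
       component_scores = comp, total = sum(comp))
}

#' HEI scores for every cart in an item table
#'
#' @param items data.frame of items for many carts (not-ranked items already
#'   removed); must carry `cart_id` and the constituent columns.
#' @param standards a `cfni_standards` set (defaults to the shipped HEI-2015
#'   standards).
#' @return data.frame: `cart_id`, one column per component, and `hei_total`,
#'   one row per cart in first-appearance order.
#' @export
score_carts <- function(items, standards = default_hei_standards()) {
  ids <- unique(items$cart_id)
  rows <- lapply(ids, function(id) {
    sc <- score_cart(items[items$cart_id == id, , drop = FALSE], standards)
    c(list(cart_id = id), as.list(sc$component_scores),
      list(hei_total = sc$total))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  rownames(out) <- NULL
  out
}
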