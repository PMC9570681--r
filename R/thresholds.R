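#' Construct or validate a tier-threshold configuration
#'
#' The HER-style stoplight scheme ranks a food item within its category by the
#' worst of three per-serving nutrients: saturated fat (g), sodium (mg) and
#' added sugar (g). A threshold configuration holds, for each of the 11 food
#' categories, a `ranked` flag and per-nutrient `green_max` / `yellow_max`
#' cutoffs (a value at or below `green_max` is green, at or below `yellow_max`
#' yellow, above it red). A nutrient may be omitted (`NULL`) to mark "no
#' threshold" for that category; it is then skipped when ranking.
#'
#' Cutoff values are configuration data, not code: the published HER Guidelines
#' tables should be transcribed into a YAML file (see
#' [read_tier_thresholds()]). The copy shipped with the package
#' (`her-thresholds-synthetic.yaml`) is a synthetic stand-in built from FDA
#' low/moderate nutrient-claim levels and is intended for demonstration and
#' simulation, not for ranking real inventory.
#'
#' @param x a named list: one entry per category, each a list with elements
#'   `ranked` (logical) and optionally `sat_fat`, `sodium`, `added_sugar`,
#'   each a list with numeric `green_max` and `yellow_max`.
#' @return an object of class `cfni_thresholds`.
#' @examples
#' thr <- as_tier_thresholds(list(
#'   grains = list(ranked = TRUE,
#'     sat_fat = list(green_max = 2, yellow_max = 5),
#'     sodium = list(green_max = 230, yellow_max = 480),
#'     added_sugar = list(green_max = 6, yellow_max = 12)),
#'   condiments_cooking_staples = list(ranked = FALSE)
#' ))
#' @export
as_tier_thresholds <- function(x) {
  if (inherits(x, "cfni_thresholds")) return(x)
  if (!is.list(x) || is.null(names(x)) || any(names(x) == "")) {
    cfni_stop("thresholds must be a named list with one entry per category",
              "cfni_config_error")
  }
  unknown <- setdiff(names(x), her_categories)
  if (length(unknown)) {
    cfni_stop(sprintf(
      "unknown categories in thresholds config: %s (allowed: %s)",
      paste(unknown, collapse = ", "), paste(her_categories, collapse = ", ")),
      "cfni_config_error")
  }
  for (cat in names(x)) {
    blk <- x[[cat]]
    if (is.null(blk$ranked) || !is.logical(blk$ranked)) {
      cfni_stop(sprintf("category '%s' needs a logical 'ranked' flag", cat),
                "cfni_config_error")
    }
    for (nut in c("sat_fat", "sodium", "added_sugar")) {
      th <- blk[[nut]]
      if (is.null(th)) next                       # "no threshold" marker
      if (!is.numeric(th$green_max) || !is.numeric(th$yellow_max) ||
          th$green_max > th$yellow_max) {
        cfni_stop(sprintf(
          "category '%s', nutrient '%s': need numeric green_max <= yellow_max",
          cat, nut), "cfni_config_error")
      }
    }
  }
  structure(x, class = "cfni_thresholds")
}

#' Read a tier-threshold configuration from YAML
#'
#' @param path path to a YAML file with one block per category (see
#'   [as_tier_thresholds()] for the structure).
#' @return a `cfni_thresholds` object.
#' @export
read_tier_thresholds <- function(path) {
  if (!file.exists(path)) {
    cfni_stop(sprintf("thresholds file not found: %s", path), "cfni_io_error")
  }
  as_tier_thresholds(yaml::read_yaml(path))
}

#' Default (synthetic) tier thresholds shipped with the package
#'
#' A full 11-category configuration in which condiments/cooking staples and
#' miscellaneous foods are not ranked. The cutoffs are a synthetic stand-in
#' based on FDA nutrient-content claim levels, shipped so the pipeline runs
#' end to end; replace with a transcription of the published HER Guidelines
#' tables for production ranking.
#'
#' @return a `cfni_thresholds` object.
#' @export
default_tier_thresholds <- function() {
  read_tier_thresholds(
    system.file("extdata", "her-thresholds-synthetic.yaml", package = "cfni",
                mustWork = TRUE))
}

#' @export
print.cfni_thresholds <- function(x, ...) {
  ranked <- vapply(x, function(b) isTRUE(b$ranked), logical(1))
  cat("Tier-threshold configuration:", length(x), "categories (",
      sum(ranked), "ranked,", sum(!ranked), "not ranked )\n")
  invisible(x)
}
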