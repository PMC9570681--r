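cart_required_cols <- c("cart_id", "item_id", "category", "weight_lb",
                        "sat_fat_g_serv", "sodium_mg_serv",
                        "added_sugar_g_serv")

#' Read a cart-item table
#'
#' Comma-separated, UTF-8, mandatory header. One row per food item with the
#' cart it belongs to, its HER category, weight, tier-determining per-serving
#' nutrients and (optionally) whole-item HEI constituent totals. An optional
#' `weight_unit` column (`lb` or `g`) is accepted; gram weights are converted
#' to pounds on read (percent-by-weight summaries are unit-invariant, pounds
#' are the storage convention).
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(weight_lb = "pounds")`.
#' @return data.frame of items (carts grouped by `cart_id`, file order
#'   preserved).
#' @export
read_cart_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    cfni_stop(sprintf("input file not found: %s", path), "cfni_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df)) {
        cfni_stop(sprintf("schema column '%s' (for '%s') not in file",
                          schema[[canon]], canon), "cfni_schema_error")
      }
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  missing <- setdiff(cart_required_cols, names(df))
  if (length(missing)) {
    cfni_stop(sprintf("missing required column(s): %s",
                      paste(missing, collapse = ", ")), "cfni_schema_error")
  }
  if ("weight_unit" %in% names(df)) {
    bad <- !df$weight_unit %in% c("lb", "g")
    if (any(bad)) {
      cfni_stop(sprintf("row %d: weight_unit must be 'lb' or 'g'",
                        which(bad)[1]), "cfni_validation_error")
    }
    df$weight_lb <- ifelse(df$weight_unit == "g",
                           df$weight_lb / 453.59237, df$weight_lb)
    df$weight_unit <- NULL
  }
  num_cols <- intersect(c("weight_lb", "sat_fat_g_serv", "sodium_mg_serv",
                          "added_sugar_g_serv", hei_constituents), names(df))
  for (cc in num_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      if (length(bad)) {
        cfni_stop(sprintf("row %d: column '%s' is not numeric", bad[1], cc),
                  "cfni_validation_error")
      }
      df[[cc]] <- as.numeric(v)
    }
  }
  if (any(df$weight_lb <= 0)) {
    cfni_stop(sprintf("row %d: weight must be strictly positive",
                      which(df$weight_lb <= 0)[1]), "cfni_validation_error")
  }
  for (cc in setdiff(num_cols, "weight_lb")) {
    if (any(df[[cc]] < 0)) {
      cfni_stop(sprintf("row %d: column '%s' must be non-negative",
                        which(df[[cc]] < 0)[1], cc), "cfni_validation_error")
    }
  }
  bad_cat <- !df$category %in% her_categories
  if (any(bad_cat)) {
    cfni_stop(sprintf("row %d: unknown category '%s' (allowed: %s)",
                      which(bad_cat)[1], df$category[which(bad_cat)[1]],
                      paste(her_categories, collapse = ", ")),
              "cfni_validation_error")
  }
  df
}

#' Write a cart-item table
#' @param items data.frame of items.
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_cart_table <- function(items, path) {
  utils::write.csv(items, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# round all numerics in a nested structure to 6 significant digits
signif_rec <- function(x, digits = 6) {
  if (is.double(x)) signif(x, digits)
  else if (is.list(x)) lapply(x, signif_rec, digits = digits)
  else if (is.data.frame(x)) as.data.frame(lapply(x, signif_rec, digits = digits))
  else x
}

#' Digest of a configuration object
#'
#' MD5 of the canonical JSON serialization; recorded in result files so a run
#' can be tied to the exact configuration that produced it.
#'
#' @param config any serializable object.
#' @return hex digest string.
#' @export
config_digest <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Write a result report deterministically
#'
#' JSON with stable key order and floats fixed at 6 significant digits, so
#' identical reports serialize byte-identically. The seed and a configuration
#' digest are embedded when supplied.
#'
#' @param report a result object (list, data.frame, fitted model, formula...).
#' @param path destination file.
#' @param seed optional integer seed to record.
#' @param config optional configuration to digest and record.
#' @return `path`, invisibly.
#' @export
write_results <- function(report, path, seed = NULL, config = NULL) {
  if (!dir.exists(dirname(path))) {
    cfni_stop(sprintf("parent directory does not exist: %s", dirname(path)),
              "cfni_io_error")
  }
  payload <- unclass(report)
  if (!is.list(payload)) payload <- list(value = payload)
  if (!is.null(seed) && is.null(payload$seed)) payload$seed <- seed
  if (!is.null(config) && is.null(payload$config_digest)) {
    payload$config_digest <- config_digest(config)
  }
  payload <- signif_rec(payload)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns", force = TRUE, pretty = TRUE)
  con <- file(path, open = "wb")           # fixed EOL across platforms
  on.exit(close(con))
  writeLines(json, con, sep = "\n")
  invisible(path)
}

#' Read back a result report
#' @param path JSON file written by [write_results()].
#' @return list.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
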