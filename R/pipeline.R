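#' Configuration of a full pipeline run
#'
#' @param seed integer seed, recorded in all outputs (default 20220921).
#' @param input path to a cart-item CSV, or `NULL` to simulate carts with
#'   [generate_catalog_and_carts()].
#' @param thresholds a `cfni_thresholds` object or YAML path (default:
#'   shipped synthetic thresholds).
#' @param standards a `cfni_standards` object or YAML path (default: shipped
#'   HEI-2015 standards).
#' @param method weight model, see [fit_index_model()] (default model 1).
#' @param k evaluation cross-validation folds (default 5).
#' @param n_carts carts to simulate when `input` is `NULL` (default 503).
#' @return list of class `cfni_run_config`.
#' @export
run_config <- function(seed = 20220921, input = NULL, thresholds = NULL,
                       standards = NULL, method = "model1_ridge_ic", k = 5,
                       n_carts = 503) {
  structure(list(seed = seed, input = input,
                 thresholds = thresholds, standards = standards,
                 method = method, k = k, n_carts = n_carts),
            class = "cfni_run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    cfni_stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
              "cfni_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' rank -> score -> fit -> transform -> evaluate, in order: tier-rank every
#' item and summarise carts, HEI-score the ranked items, fit the selected
#' weight model, rewrite it as the 0-100 index formula, then produce the
#' validation surface (tier-HEI correlations, quintile profile with trend
#' tests, k-fold cross-validated index-HEI correlation). Identical seed and
#' inputs give an identical report.
#'
#' @param config a [run_config()].
#' @return list report: `tier_summary_stats`, `tier_summaries`, `hei_scores`,
#'   `correlations`, `quintile_profile`, `fitted_model`, `index_formula`,
#'   `cfni_scores`, `cv_result`, `seed`, `config_digest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "cfni_run_config"))
  thr <- stage("config", {
    x <- config$thresholds %||% default_tier_thresholds()
    if (is.character(x)) x <- read_tier_thresholds(x)
    as_tier_thresholds(x)
  })
  std <- stage("config", {
    x <- config$standards %||% default_hei_standards()
    if (is.character(x)) x <- read_hei_standards(x)
    as_hei_standards(x)
  })
  items <- stage("input", {
    if (is.null(config$input)) {
      generate_catalog_and_carts(catalog_params(seed = config$seed),
                                 n_carts = config$n_carts)
    } else {
      read_cart_table(config$input)
    }
  })
  coll <- stage("rank", summarize_collection(items, thr))
  summaries <- coll$summaries
  ranked_items <- stage("rank", {
    items$tier <- rank_items(items, thr)
    items[items$tier != "not_ranked" & items$cart_id %in% summaries$cart_id, ,
          drop = FALSE]
  })
  hei <- stage("hei", score_carts(ranked_items, std))
  fit <- stage("fit", {
    if (config$method %in% c("model2_ridge_cv", "model2")) {
      fit_index_model(summaries, hei, method = config$method,
                      seed = config$seed)
    } else {
      fit_index_model(summaries, hei, method = config$method)
    }
  })
  formula <- stage("transform", to_index_formula(fit))
  scores <- stage("transform", cfni_score(formula, summaries))
  validation <- stage("evaluate", {
    merged <- merge(summaries, hei[c("cart_id", "hei_total")], by = "cart_id")
    corr <- lapply(c("pct_green", "pct_yellow", "pct_red"), function(tv) {
      pearson_r(merged$hei_total, merged[[tv]])
    })
    names(corr) <- c("green", "yellow", "red")
    labels <- assign_quintiles(merged$hei_total)
    qp <- quintile_profile(merged, labels)
    cv <- kfold_cv_correlation(summaries, hei, method = config$method,
                               k = config$k, seed = config$seed)
    list(correlations = corr, quintile_profile = qp, cv = cv)
  })
  list(tier_summary_stats = list(means = coll$means, sds = coll$sds,
                                 n_carts = coll$n_carts),
       tier_summaries = summaries,
       hei_scores = hei[c("cart_id", "hei_total")],
       correlations = validation$correlations,
       quintile_profile = validation$quintile_profile,
       fitted_model = unclass(fit)[c("method", "constant", "coef_green",
                                     "coef_red", "penalty")],
       index_formula = unclass(formula),
       cfni_scores = data.frame(cart_id = summaries$cart_id,
                                cfni = scores, stringsAsFactors = FALSE),
       cv_result = unclass(validation$cv),
       seed = config$seed,
       config_digest = config_digest(unclass(config)))
}
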