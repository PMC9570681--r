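#' Calibrate the composition generator to target HEI moments
#'
#' The generator draws cart compositions `(G, Y, R)` and sets
#' `HEI = c + bG*G + bR*R + e`, `e ~ Normal(0, noise_sd)`. Two free knobs are
#' not observable from marginal summaries and are set here by moment matching:
#'
#' * `corr_green_red`: chosen so that the variance of the linear predictor,
#'   `bG^2*sG^2 + bR^2*sR^2 + 2*bG*bR*rho*sG*sR`, equals
#'   `(target_cv_corr * target_hei_sd)^2` — i.e. the plane explains exactly
#'   the target fraction of HEI variance, which makes the population
#'   index-vs-HEI correlation equal `target_cv_corr`.
#' * `noise_sd = target_hei_sd * sqrt(1 - target_cv_corr^2)`, the residual SD
#'   that completes the target HEI SD.
#'
#' @param target_hei_sd target SD of HEI scores (default 11.4).
#' @param target_cv_corr target correlation between the linear predictor and
#'   HEI, in (0, 1) (default 0.585).
#' @param sd_composition SDs of (green, yellow, red) percentages; only the
#'   green and red entries enter the moment match (default
#'   `c(14.1, 11.1, 12.4)`).
#' @param gen_coef_green,gen_coef_red generating-plane slopes, HEI units per
#'   percentage point (defaults 0.270 and -0.278).
#' @return list with `corr_green_red` and `noise_sd`.
#' @export
calibrate_generator <- function(target_hei_sd = 11.4, target_cv_corr = 0.585,
                                sd_composition = c(14.1, 11.1, 12.4),
                                gen_coef_green = 0.270,
                                gen_coef_red = -0.278) {
  if (!(target_cv_corr > 0 && target_cv_corr < 1)) {
    cfni_stop("target_cv_corr must lie strictly between 0 and 1",
              "cfni_validation_error")
  }
  sg <- sd_composition[1]; sr <- sd_composition[3]
  need <- (target_cv_corr * target_hei_sd)^2
  base <- gen_coef_green^2 * sg^2 + gen_coef_red^2 * sr^2
  cross <- 2 * gen_coef_green * gen_coef_red * sg * sr   # < 0 when slopes oppose
  # need = base + rho * cross  =>  rho = (need - base) / cross
  rho <- (need - base) / cross
  if (!is.finite(rho) || rho < -1 || rho > 0) {
    attainable <- sort(base + c(0, -1) * cross)
    cfni_stop(sprintf(
      "target predictor variance %.3f unattainable: corr in [-1, 0] gives [%.3f, %.3f]",
      need, attainable[1], attainable[2]), "cfni_calibration_error")
  }
  list(corr_green_red = rho,
       noise_sd = target_hei_sd * sqrt(1 - target_cv_corr^2))
}

#' Parameters of the composition-level generator
#'
#' Defaults reproduce the study conditions: 503 carts, mean tier composition
#' (50.1, 26.0, 23.9) with SDs (14.1, 11.1, 12.4), generating plane
#' `HEI = 56.72 + 0.270*G - 0.278*R`, and `corr_green_red` / `noise_sd`
#' calibrated by [calibrate_generator()] to an HEI SD of 11.4 and a
#' predictor-HEI correlation of 0.585.
#'
#' @param n_carts number of carts (default 503).
#' @param mean_composition mean (green, yellow, red) percentages, summing to
#'   100.
#' @param sd_composition SDs of the three percentages.
#' @param corr_green_red correlation between green and red in `[-1, 0]`;
#'   `NULL` (default) to calibrate.
#' @param gen_constant,gen_coef_green,gen_coef_red generating plane.
#' @param noise_sd residual SD of HEI; `NULL` (default) to calibrate.
#' @param target_hei_sd,target_cv_corr calibration targets used when
#'   `corr_green_red` or `noise_sd` is `NULL`.
#' @param seed integer seed.
#' @return list of class `cfni_composition_params`.
#' @export
composition_params <- function(n_carts = 503,
                               mean_composition = c(50.1, 26.0, 23.9),
                               sd_composition = c(14.1, 11.1, 12.4),
                               corr_green_red = NULL,
                               gen_constant = 56.72,
                               gen_coef_green = 0.270,
                               gen_coef_red = -0.278,
                               noise_sd = NULL,
                               target_hei_sd = 11.4,
                               target_cv_corr = 0.585,
                               seed = 20220921) {
  if (abs(sum(mean_composition) - 100) > 1e-9) {
    cfni_stop("mean_composition must sum to 100", "cfni_validation_error")
  }
  if (!is_count(n_carts) || n_carts < 10) {
    cfni_stop("n_carts must be an integer >= 10", "cfni_validation_error")
  }
  if (is.null(corr_green_red) || is.null(noise_sd)) {
    cal <- calibrate_generator(target_hei_sd, target_cv_corr, sd_composition,
                               gen_coef_green, gen_coef_red)
    corr_green_red <- corr_green_red %||% cal$corr_green_red
    noise_sd <- noise_sd %||% cal$noise_sd
  }
  if (corr_green_red < -1 || corr_green_red > 0) {
    cfni_stop("corr_green_red must lie in [-1, 0]", "cfni_validation_error")
  }
  if (noise_sd < 0) cfni_stop("noise_sd must be >= 0", "cfni_validation_error")
  structure(list(n_carts = n_carts, mean_composition = mean_composition,
                 sd_composition = sd_composition,
                 corr_green_red = corr_green_red, gen_constant = gen_constant,
                 gen_coef_green = gen_coef_green, gen_coef_red = gen_coef_red,
                 noise_sd = noise_sd, seed = seed),
            class = "cfni_composition_params")
}

#' Simulate cart compositions and HEI scores
#'
#' Draws `(G, R)` from a bivariate normal with the configured means, SDs and
#' correlation, sets `Y = 100 - G - R`, and rejects draws with any component
#' outside `[0, 100]` (rejection, not clipping, to preserve the moments).
#' HEI is the generating plane plus Gaussian noise, truncated to `[0, 100]`
#' since the index is bounded.
#'
#' @param params a [composition_params()] object.
#' @return data.frame: `cart_id`, `pct_green`, `pct_yellow`, `pct_red`, `hei`.
#' @export
generate_compositions <- function(params = composition_params()) {
  stopifnot(inherits(params, "cfni_composition_params"))
  p <- params
  mu_g <- p$mean_composition[1]; mu_r <- p$mean_composition[3]
  sg <- p$sd_composition[1]; sr <- p$sd_composition[3]
  rho <- p$corr_green_red
  withr::with_seed(p$seed, {
    G <- R <- numeric(0)
    while (length(G) < p$n_carts) {
      m <- max(2L * (p$n_carts - length(G)), 100L)
      z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
      g <- mu_g + sg * z1
      r <- mu_r + sr * (rho * z1 + sqrt(1 - rho^2) * z2)
      y <- 100 - g - r
      ok <- g >= 0 & g <= 100 & r >= 0 & r <= 100 & y >= 0 & y <= 100
      G <- c(G, g[ok]); R <- c(R, r[ok])
    }
    G <- G[seq_len(p$n_carts)]; R <- R[seq_len(p$n_carts)]
    hei <- p$gen_constant + p$gen_coef_green * G + p$gen_coef_red * R +
      stats::rnorm(p$n_carts, 0, p$noise_sd)
  })
  data.frame(cart_id = sprintf("cart_%04d", seq_len(p$n_carts)),
             pct_green = G, pct_yellow = 100 - G - R, pct_red = R,
             hei = pmin(pmax(hei, 0), 100), stringsAsFactors = FALSE)
}

# ---- item-level generator ---------------------------------------------------

# Per-category distribution defaults for the item-level simulator. Nutrients
# are per serving (g / mg / g); energy and constituent densities are per pound.
# Values are plausible for shelf-stable pantry stock; they exist to exercise
# the ranker and scorer end to end, not to mimic any real inventory.
default_category_profiles <- function() {
  prof <- list(
    #                 p     wlog  satf sod  sug  kcal_lb
    fruits_vegetables = list(0.32, 0.0, 0.2,  60,  1.5,  350),
    grains            = list(0.13, -0.2, 0.5, 180,  3,   1500),
    protein           = list(0.12, 0.0, 2.0, 280,  0.5,  800),
    dairy             = list(0.09, 0.0, 2.5, 150,  6,    700),
    non_dairy_alternatives = list(0.03, 0.0, 0.5, 90, 5, 350),
    beverages         = list(0.06, 0.3, 0.1,  40, 10,    250),
    mixed_dishes      = list(0.08, 0.1, 2.5, 450,  3,    900),
    snacks            = list(0.06, -0.8, 2.0, 200, 7,   2000),
    desserts          = list(0.05, -0.5, 4.0, 220, 15,  1800),
    condiments_cooking_staples = list(0.04, -0.5, 1.0, 350, 5, 1500),
    miscellaneous     = list(0.02, -0.5, 0.5, 100, 3,    500)
  )
  out <- do.call(rbind, lapply(names(prof), function(nm) {
    v <- prof[[nm]]
    data.frame(category = nm, p_item = v[[1]], wt_meanlog = v[[2]],
               sat_fat_mean = v[[3]], sodium_mean = v[[4]],
               added_sugar_mean = v[[5]], kcal_per_lb = v[[6]],
               stringsAsFactors = FALSE)
  }))
  out$p_item <- out$p_item / sum(out$p_item)
  out
}

#' Parameters of the item-level cart simulator
#'
#' @param category_profiles data.frame of per-category sampling weights,
#'   log-weight location, mean per-serving nutrients and energy density
#'   (default [default_category_profiles()] internals).
#' @param items_mean,items_sd mean and SD of the per-cart item count, rounded
#'   and truncated to `[5, 80]` (defaults 42 and 15, matching an average
#'   pantry visit of roughly forty items).
#' @param seed integer seed.
#' @return list of class `cfni_catalog_params`.
#' @export
catalog_params <- function(category_profiles = default_category_profiles(),
                           items_mean = 42, items_sd = 15,
                           seed = 20220921) {
  needed <- c("category", "p_item", "wt_meanlog", "sat_fat_mean",
              "sodium_mean", "added_sugar_mean", "kcal_per_lb")
  if (!all(needed %in% names(category_profiles))) {
    cfni_stop("category_profiles missing required columns", "cfni_config_error")
  }
  if (any(category_profiles$p_item <= 0)) {
    cfni_stop("every category needs a positive sampling weight",
              "cfni_parameter_error")
  }
  missing_cat <- setdiff(her_categories, category_profiles$category)
  if (length(missing_cat)) {
    cfni_stop(sprintf("no profile for category: %s",
                      paste(missing_cat, collapse = ", ")),
              "cfni_parameter_error")
  }
  structure(list(category_profiles = category_profiles,
                 items_mean = items_mean, items_sd = items_sd, seed = seed),
            class = "cfni_catalog_params")
}

#' Simulate item-level carts
#'
#' Generates a cart-item table ready for [rank_items()] and [score_carts()]:
#' each cart draws 5-80 items, each item a category (all 11 categories occur
#' in expectation, including the not-ranked ones, so exclusion logic is
#' exercised), a lognormal weight, gamma-distributed per-serving nutrients
#' around the category means, and constituent totals proportional to weight
#' with category-flavoured densities.
#'
#' @param params a [catalog_params()] object.
#' @param n_carts number of carts.
#' @param seed integer seed (overrides `params$seed` when given).
#' @return data.frame in the cart-item table schema (see
#'   [read_cart_table()]).
#' @export
generate_catalog_and_carts <- function(params = catalog_params(), n_carts,
                                       seed = NULL) {
  stopifnot(inherits(params, "cfni_catalog_params"))
  seed <- seed %||% params$seed
  prof <- params$category_profiles
  withr::with_seed(seed, {
    n_items <- pmin(pmax(round(stats::rnorm(n_carts, params$items_mean,
                                            params$items_sd)), 5), 80)
    rows <- vector("list", n_carts)
    for (ci in seq_len(n_carts)) {
      k <- n_items[ci]
      cat_idx <- sample.int(nrow(prof), k, replace = TRUE, prob = prof$p_item)
      pr <- prof[cat_idx, , drop = FALSE]
      weight <- stats::rlnorm(k, meanlog = pr$wt_meanlog, sdlog = 0.5)
      gam <- function(mu) ifelse(mu > 0, stats::rgamma(k, shape = 2,
                                                       scale = mu / 2), 0)
      sat_fat <- gam(pr$sat_fat_mean)
      sodium <- gam(pr$sodium_mean)
      sugar <- gam(pr$added_sugar_mean)
      energy <- weight * pr$kcal_per_lb * stats::rlnorm(k, 0, 0.2)
      cat <- pr$category
      dens <- function(categories, per_lb) {
        weight * per_lb * (cat %in% categories) * stats::rlnorm(k, 0, 0.3)
      }
      rows[[ci]] <- data.frame(
        cart_id = sprintf("cart_%04d", ci),
        item_id = sprintf("cart_%04d_item_%03d", ci, seq_len(k)),
        category = cat, weight_lb = weight,
        sat_fat_g_serv = sat_fat, sodium_mg_serv = sodium,
        added_sugar_g_serv = sugar,
        energy = energy,
        total_fruit = dens("fruits_vegetables", 0.6) * 0.5,
        whole_fruit = dens("fruits_vegetables", 0.6) * 0.25,
        total_veg = dens("fruits_vegetables", 0.9),
        greens_beans = dens(c("fruits_vegetables", "protein"), 0.15),
        dairy = dens(c("dairy", "non_dairy_alternatives"), 1.8),
        whole_grain = dens("grains", 4.0),
        refined_grain = dens(c("grains", "snacks", "desserts",
                               "mixed_dishes"), 3.0),
        total_protein = dens(c("protein", "mixed_dishes"), 5.0),
        seafood_plant_protein = dens("protein", 1.5),
        mufa = energy * 0.010,
        pufa = energy * 0.008,
        sfa = sat_fat * pmax(weight * 4, 1),   # servings scale with weight
        sodium = sodium * pmax(weight * 4, 1),
        added_sugar = sugar * pmax(weight * 4, 1),
        stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
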