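ACTIVITY_MULTIPLIERS <- c(too_little = 1.2, light = 1.375, moderate = 1.55,
                          strong = 1.725, very_strong = 1.9)

#' Nutrient limits
#'
#' Healthy per-serving bands `[min, max]` for the six tracked nutrients.
#' The scoring rule treats eating under the minimum as better than eating
#' over the maximum, so the band is asymmetric in consequence even though
#' it is a plain interval.
#'
#' The shipped defaults are per-meal placeholder bands in the units of the
#' recipe table (grams, except cholesterol and sodium in mg); they are
#' deliberately editable because authoritative intake limits depend on
#' jurisdiction and population.
#'
#' @param limits named list: for each of `protein`, `lipids`,
#'   `carbohydrates`, `cholesterol`, `sodium`, `saturated_fat` a numeric
#'   `c(min, max)` with `0 <= min <= max`.
#' @return an object of class `nvc_limits` (named list of length-2 vectors).
#' @export
nutrient_limits <- function(limits = default_nutrient_limits()) {
  if (inherits(limits, "nvc_limits")) return(limits)
  missing_n <- setdiff(NUTRIENTS, names(limits))
  if (length(missing_n) > 0) {
    stop("nutrient limits missing for: ", paste(missing_n, collapse = ", "),
         call. = FALSE)
  }
  limits <- lapply(limits[NUTRIENTS], function(v) {
    v <- as.numeric(unlist(v))
    if (length(v) != 2 || anyNA(v) || v[1] > v[2] || v[1] < 0) {
      stop("each nutrient limit must be c(min, max) with 0 <= min <= max",
           call. = FALSE)
    }
    stats::setNames(v, c("min", "max"))
  })
  structure(limits, class = "nvc_limits")
}

#' @rdname nutrient_limits
#' @export
default_nutrient_limits <- function() {
  nutrient_limits(list(
    protein = c(15, 35),          # g
    lipids = c(10, 25),           # g total fat
    carbohydrates = c(40, 90),    # g
    cholesterol = c(20, 100),     # mg
    sodium = c(150, 600),         # mg
    saturated_fat = c(2, 8)       # g
  ))
}

#' Per-nutrient sub-score
#'
#' The three-level healthiness score of a single nutrient amount against
#' its band: 5 inside `[min, max]`, 3 below the minimum, 1 above the
#' maximum. Under-consumption is deliberately scored better than
#' over-consumption.
#'
#' @param value nutrient amount(s), `>= 0`; vectorised.
#' @param min_n,max_n the band, `min_n <= max_n`.
#' @return integer vector with values in `{1, 3, 5}`.
#' @export
nutrient_subscore <- function(value, min_n, max_n) {
  stopifnot(min_n <= max_n)
  ifelse(value >= min_n & value <= max_n, 5L, ifelse(value < min_n, 3L, 1L))
}

#' Nutrient score of recipes
#'
#' Sum of the six per-nutrient sub-scores (protein, lipids, carbohydrates,
#' cholesterol, sodium, saturated fat), so the total lies in
#' `{6, 8, ..., 30}`.
#'
#' @param recipes a recipe table (one or more rows).
#' @param limits an `nvc_limits` (default [default_nutrient_limits()]).
#' @return integer vector of totals, one per recipe row. With
#'   `by_nutrient = TRUE`, [nutrient_subscores()] returns the n x 6 matrix
#'   of individual sub-scores instead.
#' @export
nutrient_score <- function(recipes, limits = default_nutrient_limits()) {
  rowSums(nutrient_subscores(recipes, limits))
}

#' @rdname nutrient_score
#' @export
nutrient_subscores <- function(recipes, limits = default_nutrient_limits()) {
  recipes <- recipe_table(recipes)
  limits <- nutrient_limits(limits)
  m <- vapply(NUTRIENTS, function(n) {
    nutrient_subscore(recipes[[n]], limits[[n]]["min"], limits[[n]]["max"])
  }, numeric(nrow(recipes)))
  m <- matrix(m, nrow = nrow(recipes), dimnames = list(recipes$id, NUTRIENTS))
  m
}

#' Basal metabolic rate (kcal/day)
#'
#' Linear formula in weight (kg), height (cm) and age (years):
#' `10*weight + 6.25*height - 5*age + 5` for men and the same with constant
#' `+161` for women. Note the female constant: the classical
#' Mifflin-St Jeor form subtracts 161; this implementation keeps the
#' additive constant as its reference source states it, and
#' `female_constant` lets you restore the textbook value (`-161`) if
#' preferred.
#'
#' @param profile an `nvc_profile`.
#' @param female_constant additive constant for women (default 161).
#' @return kcal per day.
#' @export
bmr <- function(profile, female_constant = 161) {
  stopifnot(inherits(profile, "nvc_profile"))
  base <- 10 * profile$weight + 6.25 * profile$height - 5 * profile$age
  base + if (profile$sex == "male") 5 else female_constant
}

#' Active metabolic rate (kcal/day)
#'
#' BMR scaled by the activity-level multiplier: too_little 1.2, light
#' 1.375, moderate 1.55, strong 1.725, very_strong 1.9 (the maintenance
#' calorie table).
#'
#' @inheritParams bmr
#' @return kcal per day.
#' @export
amr <- function(profile, female_constant = 161) {
  stopifnot(inherits(profile, "nvc_profile"))
  mult <- ACTIVITY_MULTIPLIERS[[profile$activity_level]]
  bmr(profile, female_constant) * mult
}

#' Per-meal calorie band for a user
#'
#' The daily requirement (AMR) is mapped to a per-meal budget
#' `center = amr * meal_fraction`, then widened to
#' `[center*(1-tolerance), center*(1+tolerance)]`. Defaults assume three
#' equal meals and a 10% tolerance.
#'
#' @inheritParams bmr
#' @param meal_fraction fraction of the daily requirement allotted to this
#'   meal, in (0, 1].
#' @param tolerance half-width of the band relative to the center, in
#'   \[0, 1).
#' @return an object of class `nvc_band`: `c(min_cal, max_cal)` in kcal.
#' @export
calorie_band <- function(profile, meal_fraction = 1 / 3, tolerance = 0.10,
                         female_constant = 161) {
  stopifnot(meal_fraction > 0, meal_fraction <= 1,
            tolerance >= 0, tolerance < 1)
  center <- amr(profile, female_constant) * meal_fraction
  structure(c(min_cal = center * (1 - tolerance),
              max_cal = center * (1 + tolerance)),
            class = "nvc_band")
}

#' @rdname calorie_band
#' @param min_cal,max_cal explicit band bounds in kcal,
#'   `0 < min_cal <= max_cal`.
#' @export
make_band <- function(min_cal, max_cal) {
  stopifnot(min_cal > 0, min_cal <= max_cal)
  structure(c(min_cal = min_cal, max_cal = max_cal), class = "nvc_band")
}

#' Calorie (AMR) sub-score
#'
#' 5 when the recipe's calories fall inside the user's band, 3 below it
#' (under-eating scored better), 1 above it.
#'
#' @param recipe_calories kcal per serving; vectorised.
#' @param band an `nvc_band` from [calorie_band()] or [make_band()].
#' @return integer vector with values in `{1, 3, 5}`.
#' @export
amr_score <- function(recipe_calories, band) {
  stopifnot(inherits(band, "nvc_band"))
  nutrient_subscore(recipe_calories, band[["min_cal"]], band[["max_cal"]])
}

#' Individual satisfaction: liked-ingredient rate
#'
#' The fraction of a recipe's ingredient classes that the user likes,
#' `|liked ∩ ingredients| / |ingredients|`.
#'
#' @param liked character vector of liked class ids.
#' @param recipes recipe table (one or more rows).
#' @return numeric vector in \[0, 1\], one per recipe row.
#' @export
individual_satisfaction <- function(liked, recipes) {
  recipes <- recipe_table(recipes)
  liked <- tolower(trimws(liked))
  vapply(recipes$ingredient_classes, function(ing) {
    sum(ing %in% liked) / length(ing)
  }, numeric(1))
}

#' Normalised community popularity
#'
#' Ratings on the \[1, 5\] scale divided by 5 (so a rating of 4 maps to
#' 0.8).
#'
#' @param rating numeric rating(s) in \[1, 5\].
#' @return numeric in \[0.2, 1\].
#' @export
popularity <- function(rating) {
  if (any(rating < 1 | rating > 5)) {
    stop("rating must lie in [1, 5]", call. = FALSE)
  }
  rating / 5
}

#' User-satisfaction score
#'
#' Equal-weight mean of the individual liked-ingredient rate and the
#' normalised community popularity. Optionally the individual rates can be
#' max-normalised over the supplied recipe pool before averaging
#' (`max_normalize = TRUE`); by default they are used raw.
#'
#' @param profile an `nvc_profile` (its `likes` field is used).
#' @param recipes recipe table.
#' @param max_normalize divide individual rates by their pool maximum first.
#' @return numeric vector in \[0, 1\], one per recipe row.
#' @export
user_satisfaction <- function(profile, recipes, max_normalize = FALSE) {
  stopifnot(inherits(profile, "nvc_profile"))
  recipes <- recipe_table(recipes)
  ind <- individual_satisfaction(profile$likes, recipes)
  if (max_normalize && max(ind) > 0) ind <- ind / max(ind)
  (ind + popularity(recipes$rating)) / 2
}

#' Aggregation weights
#'
#' Non-negative weights for the nutrient, calorie (AMR) and
#' user-satisfaction terms; they must sum to 1.
#'
#' @param w_n,w_a,w_u weights for the nutrient, AMR and satisfaction terms.
#' @return an object of class `nvc_weights`.
#' @export
score_weights <- function(w_n = 1 / 3, w_a = 1 / 3, w_u = 1 / 3) {
  w <- c(w_n = w_n, w_a = w_a, w_u = w_u)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9) {
    stop("weights must sum to 1 (got ", format(sum(w)), ")", call. = FALSE)
  }
  structure(w, class = "nvc_weights")
}

#' Overall multi-criteria recipe score
#'
#' The weighted sum
#' `w_n * nutrientScore/30 + w_a * amrScore/5 + w_u * userSatisfaction`,
#' each term normalised to \[0, 1\] before weighting so the total also lies
#' in \[0, 1\]. With `nutrient_norm = "range"`, the nutrient term is
#' instead rescaled as `(sum - 6) / 24` so its floor is exactly 0; the
#' default `"max"` (`sum / 30`) keeps the 5/3/1 cases proportionally
#' spaced.
#'
#' @param recipes recipe table (one or more rows).
#' @param profile an `nvc_profile`.
#' @param limits an `nvc_limits`.
#' @param band an `nvc_band`.
#' @param w an `nvc_weights`.
#' @param nutrient_norm `"max"` (default) or `"range"`.
#' @param max_normalize passed to [user_satisfaction()].
#' @return numeric vector in \[0, 1\], one per recipe row.
#' @export
recipe_score <- function(recipes, profile, limits = default_nutrient_limits(),
                         band = calorie_band(profile), w = score_weights(),
                         nutrient_norm = c("max", "range"),
                         max_normalize = FALSE) {
  nutrient_norm <- match.arg(nutrient_norm)
  recipes <- recipe_table(recipes)
  stopifnot(inherits(w, "nvc_weights"))
  ns <- nutrient_score(recipes, limits)
  nterm <- if (nutrient_norm == "max") ns / 30 else (ns - 6) / 24
  aterm <- amr_score(recipes$calories, band) / 5
  uterm <- user_satisfaction(profile, recipes, max_normalize = max_normalize)
  as.numeric(w[["w_n"]] * nterm + w[["w_a"]] * aterm + w[["w_u"]] * uterm)
}

#' Healthiness label of recipes
#'
#' The mean of the seven health sub-scores (six nutrients plus the calorie
#' score) mapped onto three labels: mean >= 4 is `highly_healthy`,
#' mean >= 2.5 is `healthy`, anything lower is `unhealthy`. The thresholds
#' trisect the 1/3/5 sub-score scale and are configurable.
#'
#' @param recipes recipe table.
#' @param limits an `nvc_limits`.
#' @param band an `nvc_band`.
#' @param thresholds `c(highly, healthy)` cutoffs on the mean sub-score.
#' @return character vector of labels, one per recipe row.
#' @export
healthiness_label <- function(recipes, limits = default_nutrient_limits(),
                              band, thresholds = c(4, 2.5)) {
  recipes <- recipe_table(recipes)
  m <- cbind(nutrient_subscores(recipes, limits),
             amr = amr_score(recipes$calories, band))
  avg <- rowMeans(m)
  ifelse(avg >= thresholds[1], "highly_healthy",
         ifelse(avg >= thresholds[2], "healthy", "unhealthy"))
}
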