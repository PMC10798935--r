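#' Labelled datasets for explanation trees
#'
#' Explanation trees are trained on recipes encoded as eight numeric
#' features (the six nutrients, calories, community rating) with a label
#' per recipe.
#'
#' `build_item_dataset()` labels the catalogue from the *current user's*
#' viewpoint: recipes removed by constraint filtering or critiques, and
#' consumable recipes scoring below the `q_low` quantile, get -1;
#' consumable recipes at or above the `q_high` quantile get +1; the rest 0.
#' `build_user_dataset()` labels each historical offer with the decision
#' every user made: accept = +1, reject = -1 (duplicates are kept — the
#' same recipe may have been accepted by one user and rejected by
#' another).
#'
#' @param recipes full recipe table (catalogue).
#' @param excluded named character vector recipe id -> exclusion reason, as
#'   produced by [filter_recipes()].
#' @param scores named numeric vector of multi-criteria scores for the
#'   consumable recipes (names are recipe ids).
#' @param q_low,q_high score quantiles delimiting the negative / positive
#'   bands (defaults 0.33 / 0.67).
#' @return an object of class `nvc_dataset`: list with `features` (numeric
#'   data.frame, one row per recipe), `labels` (integer vector) and
#'   `recipe_id`.
#' @export
build_item_dataset <- function(recipes, excluded, scores,
                               q_low = 0.33, q_high = 0.67) {
  recipes <- recipe_table(recipes)
  stopifnot(q_low >= 0, q_high <= 1, q_low < q_high)
  labels <- integer(nrow(recipes))
  is_excluded <- recipes$id %in% names(excluded)
  labels[is_excluded] <- -1L
  if (length(scores) > 0) {
    lo <- stats::quantile(scores, q_low, names = FALSE, type = 7)
    hi <- stats::quantile(scores, q_high, names = FALSE, type = 7)
    sc <- scores[recipes$id]
    labels[!is_excluded & !is.na(sc) & sc < lo] <- -1L
    labels[!is_excluded & !is.na(sc) & sc >= hi] <- 1L
  }
  new_dataset(recipes[, RECIPE_FEATURES], labels, recipes$id)
}

#' @rdname build_item_dataset
#' @param history data.frame with the eight feature columns plus a
#'   `decision` column (`"accept"`/`"reject"`), e.g. from [gen_history()].
#' @export
build_user_dataset <- function(history) {
  if (is.null(history) || nrow(history) == 0) {
    stop("empty offer history: user-based strategy unavailable",
         call. = FALSE)
  }
  stopifnot(all(c(RECIPE_FEATURES, "decision") %in% names(history)))
  labels <- ifelse(history$decision == "accept", 1L, -1L)
  ids <- if ("id" %in% names(history)) as.character(history$id) else
    as.character(seq_len(nrow(history)))
  new_dataset(history[, RECIPE_FEATURES], labels, ids)
}

new_dataset <- function(features, labels, recipe_id) {
  features <- as.data.frame(lapply(features, as.numeric))
  names(features) <- RECIPE_FEATURES
  if (anyNA(features)) stop("labelled dataset has missing features",
                            call. = FALSE)
  rownames(features) <- NULL
  structure(list(features = features, labels = as.integer(labels),
                 recipe_id = recipe_id),
            class = "nvc_dataset")
}

#' Fit an explanation tree
#'
#' A CART classification tree (via \pkg{rpart}) over the eight recipe
#' features, used only to surface the most informative features — the tree
#' itself is never used for prediction. Splits minimise Gini impurity by
#' default (`criterion = "information"` switches to entropy). Feature
#' importance is the total impurity decrease of each feature's primary
#' splits, normalised to sum to 1; surrogate and competitor splits are
#' disabled so importances reflect the realised tree only.
#'
#' @param dataset an `nvc_dataset` with at least two distinct labels.
#' @param max_depth maximum tree depth.
#' @param min_leaf minimum observations in a leaf.
#' @param criterion `"gini"` or `"information"`.
#' @param seed accepted for interface stability; CART fitting is
#'   deterministic, so the seed has no effect on the model.
#' @return an object of class `nvc_tree`: list with `fit` (the rpart
#'   object), `importance` (named numeric over the eight features, summing
#'   to 1, or all zero for a stump) and `n_splits`.
#' @export
fit_tree <- function(dataset, max_depth = 4, min_leaf = 2,
                     criterion = c("gini", "information"), seed = NULL) {
  stopifnot(inherits(dataset, "nvc_dataset"))
  criterion <- match.arg(criterion)
  classes <- unique(dataset$labels)
  if (length(classes) < 2) {
    stop("cannot fit an explanation tree: every recipe has label ",
         classes, call. = FALSE)
  }
  df <- dataset$features
  df$.label <- factor(dataset$labels)
  fit <- rpart::rpart(
    .label ~ ., data = df, method = "class",
    parms = list(split = criterion),
    control = rpart::rpart.control(
      maxdepth = max_depth, minbucket = min_leaf,
      minsplit = max(2L, 2L * min_leaf), cp = 0,
      maxcompete = 0, maxsurrogate = 0, usesurrogate = 0, xval = 0
    )
  )
  imp <- stats::setNames(numeric(length(RECIPE_FEATURES)), RECIPE_FEATURES)
  n_splits <- 0L
  if (!is.null(fit$splits) && nrow(fit$splits) > 0) {
    # with competitors/surrogates disabled every row is a primary split
    gains <- tapply(fit$splits[, "improve"], rownames(fit$splits), sum)
    imp[names(gains)] <- gains
    n_splits <- nrow(fit$splits)
    if (sum(imp) > 0) imp <- imp / sum(imp)
  }
  structure(list(fit = fit, importance = imp, n_splits = n_splits),
            class = "nvc_tree")
}

#' Most informative features of an explanation tree
#'
#' The up-to-k features with positive importance, in descending importance
#' order; ties are resolved by the fixed feature order (protein, lipids,
#' carbohydrates, cholesterol, sodium, saturated_fat, calories, rating).
#'
#' @param model an `nvc_tree`.
#' @param k maximum number of features (default 3).
#' @return character vector of feature names (possibly shorter than k).
#' @export
top_features <- function(model, k = 3) {
  stopifnot(inherits(model, "nvc_tree"))
  imp <- model$importance
  keep <- imp > 0
  if (!any(keep)) return(character(0))
  nm <- names(imp)[keep]
  nm <- nm[order(-imp[keep], match(nm, RECIPE_FEATURES))]
  utils::head(nm, k)
}

#' Jaccard similarity of two recipes' ingredient sets
#'
#' `|A intersect B| / |A union B|` over ingredient-class ids.
#'
#' @param a,b single recipes (one-row recipe tables) or character vectors
#'   of ingredient-class ids.
#' @return similarity in \[0, 1\].
#' @export
recipe_jaccard <- function(a, b) {
  ing <- function(x) {
    if (is.data.frame(x)) x$ingredient_classes[[1]]
    else unique(tolower(trimws(as.character(x))))
  }
  A <- ing(a); B <- ing(b)
  stopifnot(length(A) > 0, length(B) > 0)
  length(intersect(A, B)) / length(union(A, B))
}

#' Select a contrastive counter-recipe
#'
#' From a pool of filtered and/or low-scoring recipes, pick the one most
#' similar (ingredient Jaccard) to the recommendation among those with a
#' strictly lower multi-criteria score. Ties go to the lower score, then
#' the lexicographically smaller id.
#'
#' @param recommended one-row recipe table (the current offer).
#' @param pool recipe table of potential counter-recipes.
#' @param pool_scores numeric vector of multi-criteria scores aligned with
#'   `pool` rows.
#' @param recommended_score the offer's own score.
#' @return the chosen one-row recipe table, or `NULL` when no pool recipe
#'   scores strictly below the recommendation (strategy unavailable).
#' @export
select_contrast <- function(recommended, pool, pool_scores,
                            recommended_score) {
  pool <- recipe_table(pool)
  stopifnot(length(pool_scores) == nrow(pool))
  eligible <- which(pool_scores < recommended_score &
                      pool$id != recommended$id[1])
  if (length(eligible) == 0) return(NULL)
  sims <- vapply(eligible, function(i) {
    recipe_jaccard(recommended, pool[i, ])
  }, numeric(1))
  ord <- order(-sims, pool_scores[eligible], pool$id[eligible],
               method = "radix")
  pool[eligible[ord[1]], , drop = FALSE]
}

#' Contrastive feature partition
#'
#' Compares the counter-recipe with the recommendation feature by feature:
#' the six nutrient sub-scores, the calorie sub-score and a taste score
#' (the liked-ingredient rate). A feature where the counter-recipe scores
#' strictly lower goes into the negative set `eps_minus` (reasons to avoid
#' the counter-recipe); every other feature goes into `eps_plus`.
#'
#' @param recommended,counter one-row recipe tables.
#' @param limits an `nvc_limits`.
#' @param band an `nvc_band`.
#' @param profile an `nvc_profile` (for the taste comparison).
#' @return list with character vectors `eps_plus` and `eps_minus`; together
#'   they always partition the full feature list.
#' @export
contrast_features <- function(recommended, counter,
                              limits = default_nutrient_limits(), band,
                              profile) {
  sub <- function(r) {
    c(nutrient_subscores(r, limits)[1, ],
      calories = amr_score(r$calories, band),
      taste = individual_satisfaction(profile$likes, r))
  }
  s_rec <- sub(recipe_table(recommended))
  s_cnt <- sub(recipe_table(counter))
  worse <- s_cnt < s_rec
  list(eps_plus = names(s_rec)[!worse], eps_minus = names(s_rec)[worse])
}

#' Qualitative feature levels of a recipe
#'
#' Maps each numeric feature of a recipe to the qualitative level used by
#' the phrase repository: nutrients score 5 -> "sufficient", 3 -> "low",
#' 1 -> "high"; calories 5 -> "appropriate", 3 -> "low", 1 -> "high";
#' rating >= 4 -> "high", >= 2.5 -> "moderate", else "low".
#'
#' @param recipe one-row recipe table.
#' @param limits an `nvc_limits`.
#' @param band an `nvc_band`.
#' @return named character vector over the eight features.
#' @export
feature_levels <- function(recipe, limits = default_nutrient_limits(), band) {
  recipe <- recipe_table(recipe)
  subs <- nutrient_subscores(recipe, limits)[1, ]
  lv <- vapply(subs, function(s) {
    switch(as.character(s), "5" = "sufficient", "3" = "low", "high")
  }, character(1))
  cal <- switch(as.character(amr_score(recipe$calories, band)),
                "5" = "appropriate", "3" = "low", "high")
  rat <- if (recipe$rating >= 4) "high" else if (recipe$rating >= 2.5)
    "moderate" else "low"
  c(lv, calories = cal, rating = rat)
}

#' Construct an explanation object
#'
#' Normally produced by [next_explanation()]; exposed for testing and for
#' custom pipelines. `realize()` turns the structured explanation into its
#' final sentence through the phrase repository; the output is a pure
#' function of the inputs.
#'
#' @param strategy `"item_based"`, `"user_based"`, `"contrastive"` or
#'   `"fallback"`.
#' @param features ordered character vector of feature names (tree-based
#'   strategies).
#' @param levels named character vector feature -> qualitative level.
#' @param counter_recipe counter-recipe id (contrastive only).
#' @param counter_name counter-recipe display name (contrastive only).
#' @param eps_plus,eps_minus contrastive feature partition.
#' @param text realised sentence; filled in by [realize()].
#' @return an object of class `nvc_explanation`.
#' @export
explanation <- function(strategy, features = character(0),
                        levels = character(0), counter_recipe = NULL,
                        counter_name = NULL, eps_plus = NULL,
                        eps_minus = NULL, text = NULL) {
  strategy <- match.arg(strategy, c("item_based", "user_based",
                                    "contrastive", "fallback", "none"))
  structure(list(strategy = strategy, features = features, levels = levels,
                 counter_recipe = counter_recipe, counter_name = counter_name,
                 eps_plus = eps_plus, eps_minus = eps_minus, text = text),
            class = "nvc_explanation")
}

#' @export
print.nvc_explanation <- function(x, ...) {
  cat("<nvc_explanation> [", x$strategy, "] ", x$text, "\n", sep = "")
  invisible(x)
}

#' @rdname explanation
#' @param expl an `nvc_explanation` (text may be empty).
#' @param phrases a phrase repository from [default_phrases()] or
#'   [load_phrases()].
#' @export
realize <- function(expl, phrases = default_phrases()) {
  stopifnot(inherits(expl, "nvc_explanation"))
  get_phrase <- function(feature, level) {
    p <- phrases$phrases[[feature]][[level]]
    if (is.null(p)) {
      stop("phrase repository has no entry for (", feature, ", ", level,
           ")", call. = FALSE)
    }
    p
  }
  join <- function(x) {
    if (length(x) == 1) x
    else paste(paste(x[-length(x)], collapse = ", "), "and", x[length(x)])
  }
  fill <- function(template, slots) {
    for (nm in names(slots)) {
      template <- gsub(paste0("{", nm, "}"), slots[[nm]], template,
                       fixed = TRUE)
    }
    template
  }
  if (expl$strategy %in% c("item_based", "user_based")) {
    if (length(expl$features) == 0) {
      stop("tree-based explanation has no features to realise",
           call. = FALSE)
    }
    clauses <- vapply(expl$features,
                      function(f) get_phrase(f, expl$levels[[f]]),
                      character(1))
    text <- fill(phrases$templates$item_user,
                 list(subject = phrases$subject, clauses = join(clauses)))
  } else if (expl$strategy == "contrastive") {
    if (length(expl$eps_minus) == 0) {
      stop("contrastive explanation needs a non-empty negative feature set",
           call. = FALSE)
    }
    neg <- vapply(expl$eps_minus, function(f) get_phrase(f, "worse"),
                  character(1))
    pos_feats <- utils::head(expl$eps_plus, 1)
    if (length(pos_feats) == 0) pos_feats <- utils::head(expl$eps_minus, 1)
    pos <- vapply(pos_feats, function(f) get_phrase(f, "better"),
                  character(1))
    text <- fill(phrases$templates$contrastive,
                 list(subject = phrases$subject, counter = expl$counter_name,
                      neg_clauses = join(neg), pos_clauses = join(pos)))
  } else {
    stop("cannot realise strategy '", expl$strategy, "'", call. = FALSE)
  }
  expl$text <- text
  expl
}
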